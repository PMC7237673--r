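test_that("distribution summaries recover known moments", {
  norm <- rggd(2e5, 2, seed = 1)
  expect_lt(abs(dist_summary(norm)$excess_kurtosis), 0.05)
  lap <- rggd(2e5, 1, seed = 1)
  expect_lt(abs(dist_summary(lap)$excess_kurtosis - 3), 0.2)

  # reflecting any sample about its mean kills the odd moments exactly
  set.seed(2)
  x <- rexp(500)
  sym <- c(x, 2 * mean(x) - x)
  expect_equal(dist_summary(sym)$skewness, 0, tolerance = 1e-12)

  expect_error(dist_summary(c(1, 2, 3)), "4")
})

test_that("Gaussian PDF model has the right density, mass and shift behaviour", {
  s <- list(mean = 0, sd = 1)
  expect_lt(abs(gaussian_pdf_model(s, 0) - 0.3989), 5e-5)
  grid <- seq(-8, 8, by = 0.01)
  dens <- gaussian_pdf_model(s, grid)
  expect_equal(sum(dens) * 0.01, 1, tolerance = 1e-3)
  shifted <- gaussian_pdf_model(list(mean = 2, sd = 1), grid + 2)
  expect_equal(shifted, dens, tolerance = 1e-12)
  expect_error(gaussian_pdf_model(list(mean = 0, sd = 0), 0), "positive")
})

test_that("the ECDF assigns mass 1/n with right-continuity and ties", {
  e <- ecdf_sample(c(1, 2, 3))
  expect_equal(e$fun(2), 2 / 3)
  expect_equal(e$fun(0), 0)
  expect_equal(e$fun(3), 1)
  expect_equal(e$fun(100), 1)
  tied <- ecdf_sample(c(1, 1, 2))
  expect_equal(tied$fun(1), 2 / 3)
  expect_error(ecdf_sample(numeric(0)), "non-empty")
  # non-decreasing step function in [0, 1]
  set.seed(3)
  e2 <- ecdf_sample(rnorm(50))
  grid <- seq(-4, 4, length.out = 500)
  v <- e2$fun(grid)
  expect_true(all(diff(v) >= 0) && all(v >= 0 & v <= 1))
})

test_that("two-sample KS statistic handles the degenerate cases", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(ks_two_sample(rep(0, 3), rep(1, 3))$statistic, 1)
})

test_that("KS statistic matches a dense-grid brute force on random pairs", {
  set.seed(11)
  for (i in 1:30) {
    a <- rnorm(sample(20:200, 1))
    b <- rnorm(sample(20:200, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$statistic, ks_brute(a, b),
                 tolerance = 1e-12)
  }
})

test_that("KS p-value agrees with the reference asymptotic implementation", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(150)
    b <- rnorm(150, mean = runif(1, 0, 0.5))
    ours <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-5)
  }
})

test_that("primitive-vs-activation comparison reduces KS correctly", {
  set.seed(13)
  x <- matrix(runif(5 * 200), 5)
  h <- matrix(runif(2 * 200), 2)
  cmp <- ks_compare(x, h, normalise = "raw")
  # d_max equals the maximum over all brute-force pairs
  brute <- max(vapply(1:5, function(l) max(
    ks_brute(x[l, ], h[1, ]), ks_brute(x[l, ], h[2, ])), numeric(1)))
  expect_equal(cmp$d_max, brute, tolerance = 1e-12)
  expect_equal(cmp$d_k, apply(cmp$d, 2, max))
  expect_true(all(cmp$d >= 0 & cmp$d <= 1))

  # primitives copied from muscle rows agree perfectly on those pairs
  hcopy <- x[c(2, 4), ]
  cmp2 <- ks_compare(x, hcopy, normalise = "raw")
  expect_equal(unname(cmp2$d[2, 1]), 0)
  expect_equal(unname(cmp2$d[4, 2]), 0)
  expect_equal(unname(cmp2$p[2, 1]), 1)

  # agreement boundary cases follow the p-value field exactly
  expect_equal(100 * mean(cmp$p >= 0.05), cmp$agreement_pct)
  expect_error(ks_compare(x, matrix(runif(5 * 200), 5)), "less")
})

test_that("d_max is invariant to muscle and primitive relabelling", {
  set.seed(14)
  x <- matrix(runif(6 * 100), 6)
  h <- matrix(runif(3 * 100), 3)
  a <- ks_compare(x, h)
  b <- ks_compare(x[sample(6), ], h[sample(3), ])
  expect_equal(a$d_max, b$d_max, tolerance = 1e-12)
  expect_equal(a$agreement_pct, b$agreement_pct)
})

test_that("agreement and d_max are invariant to a shared affine rescaling", {
  set.seed(15)
  x <- matrix(runif(5 * 150), 5)
  h <- matrix(runif(2 * 150), 2)
  a <- ks_compare(x, h, normalise = "raw")
  b <- ks_compare(0.25 * x + 3, 0.25 * h + 3, normalise = "raw")
  expect_equal(a$d_max, b$d_max, tolerance = 1e-12)
  expect_equal(a$agreement_pct, b$agreement_pct)
})

test_that("KS agreement approaches the nominal 95% level under the null", {
  set.seed(16)
  ag <- replicate(120, {
    x <- matrix(runif(5 * 200), 5)
    h <- matrix(runif(2 * 200), 2)
    ks_compare(x, h, normalise = "raw")$agreement_pct
  })
  # the asymptotic two-sample test is slightly conservative at n = 200,
  # so agreement sits at or a little above 95%
  expect_lt(abs(mean(ag) - 95), 2.5)
})

test_that("KS comparisons flatten to a long-format table", {
  set.seed(17)
  x <- matrix(runif(4 * 80), 4, dimnames = list(paste0("m", 1:4), NULL))
  cmp <- ks_compare(x, matrix(runif(2 * 80), 2), normalise = "raw")
  df <- as.data.frame(cmp)
  expect_equal(nrow(df), 8)
  expect_equal(df$d[df$muscle == "m3" & df$primitive == 2],
               unname(cmp$d[3, 2]))
  expect_equal(mean(df$agrees) * 100, cmp$agreement_pct)
})
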