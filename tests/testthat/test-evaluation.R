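test_that("VAF has the right fixed points and matches the loop oracle", {
  set.seed(21)
  x <- matrix(runif(12), 3, 4)
  expect_equal(vaf(x, x), 1)
  expect_equal(vaf(x, x * 0), 0)
  for (i in 1:20) {
    a <- matrix(runif(12), 3, 4)
    b <- matrix(runif(12), 3, 4)
    expect_equal(vaf(a, b), vaf_loop(a, b), tolerance = 1e-12)
  }
  expect_error(vaf(x * 0, x), "all-zero")
})

test_that("synergy-count selection applies the VAF-threshold rule", {
  sim <- simulate_synergy_dataset(noise_sd = 0.05, seed = 3)
  k <- select_synergy_count(sim$x, seed = 1)
  expect_equal(as.integer(k), 3L)
  expect_true(attr(k, "reached"))
  expect_true(all(attr(k, "vaf")[, "3"] > 0.85))

  expect_equal(as.integer(select_synergy_count(sim$x, threshold = 0,
                                               seed = 1)), 2L)
  expect_warning(
    kmax <- select_synergy_count(sim$x, methods = "nmf", threshold = 1,
                                 k_range = 2:4, seed = 1),
    "not reached")
  expect_equal(as.integer(kmax), 4L)
  expect_error(select_synergy_count(sim$x, methods = character(0)),
               "non-empty")
})

test_that("score_trials produces one record per trial and method, reproducibly", {
  trials <- lapply(1:4, function(s)
    simulate_synergy_dataset(noise_sd = 0.05, seed = s)$x)
  sc <- score_trials(trials, k = 3, seed = 7)
  expect_equal(nrow(sc), 16)
  expect_setequal(unique(sc$method), c("nmf", "pca", "ica", "fa"))
  expect_true(all(sc$vaf <= 1 & sc$d_max >= 0 & sc$d_max <= 1))
  expect_true(all(sc$agreement_pct >= 0 & sc$agreement_pct <= 100))

  again <- score_trials(trials, k = 3, seed = 7)
  expect_identical(sc, again)

  # deterministic methods identical across repeat scoring even unseeded
  p1 <- score_trials(trials[1], methods = "pca", k = 3)
  p2 <- score_trials(trials[1], methods = "pca", k = 3)
  expect_equal(p1$vaf, p2$vaf)
})

test_that("every method clears 85% VAF at K = 3 on noiseless synthetic data", {
  sim <- simulate_synergy_dataset(noise_sd = 0, seed = 5)
  sc <- score_trials(list(sim$x), k = 3, seed = 5)
  expect_true(all(sc$vaf >= 0.85))
})

test_that("NMF mean VAF is not materially below any other method", {
  vafs <- vapply(1:8, function(s) {
    x <- simulate_synergy_dataset(noise_sd = 0.05, seed = s)$x
    vapply(c("nmf", "pca", "ica", "fa"), function(m)
      synergy(x, m, 3, seed = s)$vaf, numeric(1))
  }, numeric(4))
  mu <- rowMeans(vafs)
  expect_true(all(mu["nmf"] >= mu - 0.02))
})

test_that("repeated-measures ANOVA across methods behaves classically", {
  set.seed(22)
  # identical scores: no effect
  flat <- expand.grid(subject = 1:5, method = c("nmf", "pca", "ica"))
  flat$vaf <- 0.9
  cmp <- compare_methods(flat, "vaf")
  expect_equal(cmp$anova$F, 0)
  expect_equal(cmp$anova$p, 1)
  expect_true(all(cmp$pairwise$p_bonferroni == 1))

  # two methods: F equals the squared paired-t statistic
  two <- expand.grid(subject = 1:8, method = c("nmf", "pca"))
  two$vaf <- 0.9 + rnorm(16, 0, 0.02)
  cmp2 <- compare_methods(two, "vaf")
  wide <- reshape(two, idvar = "subject", timevar = "method",
                  direction = "wide")
  tt <- t.test(wide$vaf.nmf, wide$vaf.pca, paired = TRUE)
  expect_equal(cmp2$anova$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(cmp2$anova$p, tt$p.value, tolerance = 1e-8)

  # Bonferroni is exactly min(1, m * p_raw)
  three <- expand.grid(subject = 1:6, method = c("nmf", "pca", "ica"))
  three$vaf <- 0.9 + rnorm(18, 0, 0.02)
  cmp3 <- compare_methods(three, "vaf")
  expect_equal(cmp3$pairwise$p_bonferroni,
               pmin(1, nrow(cmp3$pairwise) * cmp3$pairwise$p_raw))

  # unbalanced designs are refused with a clear message
  expect_error(compare_methods(flat[-1, ], "vaf"), "unbalanced")
})
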