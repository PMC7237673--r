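sim0 <- simulate_synergy_dataset(noise_sd = 0, seed = 3)
simn <- simulate_synergy_dataset(noise_sd = 0.05, seed = 3)

test_that("NMF factorises exact low-rank data and stays non-negative", {
  fit <- synergy(sim0$x, "nmf", 3, seed = 1)
  expect_true(all(fit$w >= 0))
  expect_true(all(fit$h >= 0))
  expect_gte(fit$vaf, 0.999)
  rel_err <- sqrt(sum((sim0$x - fitted(fit))^2) / sum(sim0$x^2))
  expect_lte(rel_err, 1e-3)
})

test_that("NMF multiplicative updates have a monotone objective", {
  for (s in 1:10) {
    x <- matrix(stats::runif(8 * 40), 8)
    fit <- synergy(x, "nmf", 3, seed = s, restarts = 1)
    expect_true(all(diff(fit$objective) <= 1e-12))
  }
})

test_that("NMF rejects invalid input", {
  x <- matrix(runif(40), 4)
  expect_error(synergy(x - 1, "nmf", 2), "non-negative")
  expect_error(synergy(x, "nmf", 5), "between")
})

test_that("NMF VAF does not degrade from K = L-1 to K = L", {
  set.seed(8)
  x <- matrix(runif(6 * 50), 6)
  v5 <- synergy(x, "nmf", 5, seed = 2, restarts = 15)$vaf
  v6 <- synergy(x, "nmf", 6, seed = 2, restarts = 15)$vaf
  expect_gte(v6, v5 - 1e-6)
})

test_that("PCA reconstructs exactly at full rank and matches Eckart-Young", {
  full <- synergy(simn$x, "pca", 10)
  expect_equal(fitted(full), simn$x, tolerance = 1e-10)
  expect_equal(full$vaf, 1, tolerance = 1e-10)

  r3 <- synergy(sim0$x, "pca", 3)
  expect_equal(r3$vaf, 1, tolerance = 1e-10)

  # residual energy equals the tail singular-value energy of centred data
  k <- 3
  fitk <- synergy(simn$x, "pca", k)
  d <- svd(simn$x - rowMeans(simn$x))$d
  expect_equal(sum((simn$x - fitted(fitk))^2), sum(d[(k + 1):10]^2),
               tolerance = 1e-8)

  # primitives mutually orthogonal (orthonormal up to the peak-1 scaling)
  g <- fitk$h %*% t(fitk$h)
  expect_lt(max(abs(g[upper.tri(g)])) / min(diag(g)), 1e-8)
})

test_that("PCA VAF is non-decreasing in K", {
  v <- vapply(2:6, function(k) synergy(simn$x, "pca", k)$vaf, numeric(1))
  expect_true(all(diff(v) >= -1e-12))
})

test_that("ICA separates independent Laplacian sources", {
  s_true <- rbind(rggd(1000, 1, seed = 11), rggd(1000, 1, seed = 12))
  mix <- matrix(c(1, 0.6, 0.4, 1), 2, 2)
  x <- mix %*% s_true
  fit <- synergy(x, "ica", 2, seed = 5)
  co <- abs(stats::cor(t(fit$h), t(s_true)))
  aligned <- max(min(co[1, 1], co[2, 2]), min(co[1, 2], co[2, 1]))
  expect_gte(aligned, 0.95)
})

test_that("ICA primitives are uncorrelated and full-rank ICA is lossless", {
  fit <- synergy(simn$x, "ica", 3, seed = 2)
  co <- stats::cor(t(fit$h))
  expect_lt(max(abs(co[upper.tri(co)])), 1e-6)
  expect_equal(synergy(simn$x, "ica", 10, seed = 2)$vaf, 1,
               tolerance = 1e-8)
})

test_that("FA reconstructs low-rank data and reports the eigenvalue rule", {
  expect_gte(synergy(sim0$x, "fa", 3)$vaf, 0.999)
  expect_equal(synergy(simn$x, "fa", 10)$vaf, 1, tolerance = 1e-8)
  rule <- fa_eigenvalue_rule(simn$x)
  expect_equal(rule$k, 3)           # three dominant correlation eigenvalues
  expect_equal(sum(rule$eigenvalues), 10, tolerance = 1e-8)
})

test_that("all primitives peak at 1 and reconstruction is renormalisation-invariant", {
  for (m in c("nmf", "pca", "ica", "fa")) {
    fit <- synergy(simn$x, m, 3, seed = 4)
    expect_equal(unname(apply(abs(fit$h), 1, max)), rep(1, 3),
                 tolerance = 1e-12)
    expect_equal(fitted(fit), fit$w %*% fit$h + fit$offset,
                 tolerance = 1e-12)
  }
})

test_that("primitive skewness is non-negative after the sign fix", {
  for (m in c("pca", "ica", "fa")) {
    fit <- synergy(simn$x, m, 3, seed = 4)
    sk <- apply(fit$h, 1, function(v) mean((v - mean(v))^3) / stats::sd(v)^3)
    expect_true(all(sk >= -1e-10))
  }
})

test_that("reconstruct() is pure and consistent with fitted()", {
  fit <- synergy(simn$x, "nmf", 3, seed = 1)
  r1 <- reconstruct(fit)
  r2 <- reconstruct(fit)
  expect_identical(r1, r2)
  expect_equal(r1, fitted(fit), tolerance = 1e-12)
  expect_true(all(r1 >= 0))
  p <- synergy(simn$x, "pca", 10)
  expect_equal(reconstruct(p), simn$x, tolerance = 1e-8)
})

test_that("reconstruction error statistics match brute-force oracles", {
  set.seed(6)
  x <- matrix(runif(12), 3, 4)
  x_hat <- matrix(runif(12), 3, 4)
  st <- reconstruction_error_stats(x, x_hat)
  expect_equal(st$mse, mse_loop(x, x_hat), tolerance = 1e-12)
  expect_equal(reconstruction_error_stats(x, x)$var_e, 0)
  expect_equal(reconstruction_error_stats(x, x * 0)$mse, mean(x^2),
               tolerance = 1e-12)
})

test_that("NMF recovers ground-truth weights at low noise", {
  cosines <- vapply(1:10, function(s) {
    sim <- simulate_synergy_dataset(noise_sd = 0.02, seed = s)
    fit <- synergy(sim$x, "nmf", 3, seed = s)
    match_synergies(coef(fit), sim$w_true)$mean_cosine
  }, numeric(1))
  expect_gte(mean(cosines), 0.9)
})

test_that("greedy synergy matching agrees with exhaustive permutation search", {
  for (s in 1:5) {
    set.seed(s)
    w_ref <- matrix(runif(10 * 3), 10)
    w_est <- w_ref[, sample(3)] + matrix(rnorm(30, 0, 0.05), 10)
    expect_equal(match_synergies(w_est, w_ref)$mean_cosine,
                 exhaustive_match(w_est, w_ref), tolerance = 1e-12)
  }
})
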