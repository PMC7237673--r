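fs <- 1500

test_that("band-pass preserves the passband and removes DC and drift", {
  t <- seq(0, 1, by = 1 / fs)
  mid <- sin(2 * pi * 200 * t)                    # passband centre
  out <- emg_bandpass(mid, fs)
  core <- seq(100, length(t) - 100)               # ignore edge samples
  expect_lt(abs(max(abs(out[core])) - 1), 0.01)

  dc <- rep(1, length(t))
  expect_lt(max(abs(emg_bandpass(dc, fs))), 1e-6)

  # 5 Hz attenuation agrees with the designed filter's magnitude response
  # (steady state away from the edge transients)
  slow <- sin(2 * pi * 5 * t)
  steady <- seq(300, length(t) - 300)
  att <- max(abs(emg_bandpass(slow, fs)[steady]))
  flt <- signal::butter(4, c(30, 400) / (fs / 2), type = "pass")
  w <- 2 * pi * 5 / fs   # evaluate H(e^{iw}) from the coefficients directly
  hof <- function(cf) sum(cf * exp(-1i * w * (seq_along(cf) - 1)))
  hmag <- Mod(hof(flt$b) / hof(flt$a))^2          # forward-backward pass
  expect_lt(20 * log10(att), -40)
  expect_equal(att, hmag, tolerance = 0.01)
})

test_that("band-pass validates its edges", {
  x <- matrix(rnorm(200), 1)
  expect_error(emg_bandpass(x, fs, low = 30, high = 800), "fs/2")
  expect_error(emg_bandpass(x, fs, low = 0), "low")
})

test_that("linear envelope tracks rectified intensity", {
  expect_equal(emg_envelope(rep(0, 1000), fs), rep(0, 1000))
  # rectified DC passes the low-pass
  const <- emg_envelope(rep(-0.5, 2000), fs)
  expect_lt(max(abs(const[500:1500] - 0.5)), 1e-3)
  # envelope peak lies where a moving-RMS oracle peaks
  set.seed(4)
  n <- 3000
  burst <- exp(-((seq_len(n) - 1500) / 150)^2)
  x <- rnorm(n) * burst
  env <- emg_envelope(x, fs)
  rms <- moving_rms(x, fs)
  expect_lt(abs(which.max(env) - which.max(rms)), 0.167 * fs)
  expect_true(all(env >= 0))
})

test_that("envelope is zero-lag on a symmetric burst", {
  n <- 3000
  burst <- exp(-((seq_len(n) - 1500) / 120)^2)
  env <- emg_envelope(burst, fs)
  expect_lte(abs(which.max(env) - 1500), 1)
})

test_that("cycle normalisation yields the L x n_points contract", {
  set.seed(2)
  env <- matrix(abs(rnorm(10 * 700)), 10)
  act <- normalise_cycle(env, c(1, 700))
  expect_equal(dim(act), c(10, 200))
  expect_equal(unname(apply(act, 1, max)), rep(1, 10))

  # pure rescaling when already at n_points
  row <- matrix(2 * exp(-((1:200 - 100) / 30)^2), 1)
  out <- normalise_cycle(row, c(1, 200))
  expect_equal(max(out), 1)
  expect_equal(as.vector(out), as.vector(row) / 2, tolerance = 1e-12)

  # linear ramp stays linear with endpoints preserved
  ramp <- matrix(seq(0, 1, length.out = 400), 1)
  r <- normalise_cycle(ramp, c(1, 400))
  expect_equal(as.vector(r), seq(0, 1, length.out = 200), tolerance = 1e-12)

  # dead channels stay zero, with a message rather than an error
  env[3, ] <- 0
  expect_message(act <- normalise_cycle(env, c(1, 700)), "zero")
  expect_true(all(act[3, ] == 0))

  expect_error(normalise_cycle(env, c(10, 10)), "span")
})

test_that("the full chain gives a 10 x 200 activation matrix for any trial length", {
  for (cond in c("walk", "fast_run")) {
    x <- preprocess_trial(simulate_emg_trial(cond, seed = 5))
    expect_equal(dim(x), c(10, 200))
    expect_true(all(x >= 0 & x <= 1))
    expect_equal(unname(apply(x, 1, max)), rep(1, 10))
  }
})

test_that("activation kurtosis is stable across envelope cut-offs 6/8/10 Hz", {
  # pooled over a few trials, as the amplitude-distribution summaries are
  # reported over trials rather than per single stride
  trials <- lapply(1:3, function(s) simulate_emg_trial("walk", seed = s))
  k <- vapply(c(6, 8, 10), function(co)
    dist_summary(unlist(lapply(trials, function(tr)
      as.vector(preprocess_trial(tr, envelope_cutoff = co)))))$excess_kurtosis,
    numeric(1))
  expect_lt(max(k) - min(k), 0.15)
})
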