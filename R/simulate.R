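#' Reference gait-speed conditions
#'
#' Returns the four gait-speed conditions used throughout the package, each
#' with the target excess kurtosis of the raw-EMG amplitude distribution and
#' a typical stride (toe-off to toe-off) duration. The kurtosis targets
#' encode the documented Laplacian-to-Gaussian transition of surface EMG as
#' gait speed increases: the amplitude distribution of walking EMG is
#' strongly super-Gaussian (excess kurtosis about 1.75) and flattens towards
#' Gaussian at fast running (about 1.1).
#'
#' @return A data frame with columns `label`, `target_excess_kurtosis` and
#'   `cycle_duration` (seconds), ordered by increasing speed.
#' @examples
#' speed_conditions()
#' @export
speed_conditions <- function() {
  data.frame(
    label = c("walk", "slow_run", "moderate_run", "fast_run"),
    target_excess_kurtosis = c(1.75, 1.45, 1.29, 1.10),
    cycle_duration = c(1.10, 0.78, 0.70, 0.62),
    stringsAsFactors = FALSE
  )
}

#' Look up or construct a gait-speed condition
#'
#' @param label One of `"walk"`, `"slow_run"`, `"moderate_run"`,
#'   `"fast_run"`, or an existing `speed_condition` object (returned
#'   unchanged).
#' @param target_excess_kurtosis,cycle_duration Optional overrides.
#' @return A list of class `speed_condition` with fields `label`,
#'   `target_excess_kurtosis` and `cycle_duration`.
#' @export
speed_condition <- function(label, target_excess_kurtosis = NULL,
                            cycle_duration = NULL) {
  if (inherits(label, "speed_condition")) return(label)
  tab <- speed_conditions()
  label <- match.arg(label, tab$label)
  row <- tab[tab$label == label, ]
  out <- list(
    label = label,
    target_excess_kurtosis = target_excess_kurtosis %||% row$target_excess_kurtosis,
    cycle_duration = cycle_duration %||% row$cycle_duration
  )
  if (out$cycle_duration <= 0) stop_invalid("cycle_duration must be positive")
  class(out) <- "speed_condition"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sum-of-Gaussian-bursts gait envelope on the unit cycle, with a tonic
# baseline. The baseline keeps the envelope's fourth-moment ratio
# mean(e^4)/mean(e^2)^2 low enough that a generalized-Gaussian carrier can
# be calibrated to any of the condition kurtosis targets (the product
# carrier x envelope multiplies the carrier's fourth-moment ratio by that
# envelope ratio).
burst_envelope <- function(t, centres, widths, amps, baseline) {
  e <- rep(baseline, length(t))
  for (j in seq_along(centres))
    e <- e + amps[j] * exp(-(t - centres[j])^2 / (2 * widths[j]^2))
  e
}

#' Simulate one raw surface-EMG trial
#'
#' Generates a gait-like multi-channel raw EMG trial: each channel is a
#' zero-mean generalized-Gaussian carrier modulated by a channel-specific
#' sum-of-Gaussian-bursts gait envelope, spanning one gait cycle (toe-off to
#' toe-off). The carrier shape of each channel is calibrated analytically so
#' that the channel's amplitude distribution attains the condition's target
#' excess kurtosis: for a deterministic envelope \eqn{e(t)} and independent
#' carrier \eqn{c}, the pooled fourth-moment ratio of \eqn{c\,e} is the
#' carrier's ratio times \eqn{\overline{e^4}/(\overline{e^2})^2}, so the
#' required carrier kurtosis is solved in closed form and mapped to a GGD
#' shape with [ggd_shape_for_kurtosis()]. Channels are scaled to unit RMS so
#' the pooled (all-channel) kurtosis matches the per-channel target.
#'
#' Each channel consumes an independent sub-stream derived from `seed`, so
#' changing `n_channels` never reshuffles the other channels.
#'
#' @param condition A condition label or [speed_condition()] object.
#' @param n_channels Number of EMG channels (default 10 lower-limb muscles).
#' @param fs Sampling rate in Hz (default 1500). Must be at least 800 Hz so
#'   that a 30--400 Hz band-pass remains below Nyquist.
#' @param seed Optional integer seed for full reproducibility.
#' @return An object of class `emg_trial`: list with `signal` (channels x
#'   samples matrix), `fs`, `events` (first and last sample of the cycle),
#'   `channel_labels`, `condition`, `seed`.
#' @examples
#' tr <- simulate_emg_trial("walk", seed = 1)
#' dim(tr$signal)
#' @export
simulate_emg_trial <- function(condition, n_channels = 10, fs = 1500,
                               seed = NULL) {
  cond <- speed_condition(condition)
  if (length(fs) != 1L || !is.finite(fs) || fs < 800)
    stop_invalid("'fs' must be at least 800 Hz (band-pass upper edge 400 Hz)")
  if (n_channels < 1) stop_invalid("'n_channels' must be positive")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)

  n <- max(2L, as.integer(round(cond$cycle_duration * fs)))
  t <- (seq_len(n) - 1) / n
  target <- cond$target_excess_kurtosis
  sig <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    sig[ch, ] <- with_seed(derive_seed(seed, ch), {
      # envelope parameters are always drawn for 3 bursts so the stream
      # layout is identical across conditions (common random numbers keep
      # pooled kurtosis monotone in the condition target at fixed seed)
      n_bursts <- sample(1:3, 1)
      # stratified burst centres spanning the cycle: one burst per stratum
      # with jitter, so bursts cannot stack into an envelope too peaky for
      # the carrier calibration to compensate
      u <- stats::runif(3)
      centres <- 0.1 + 0.8 * ((seq_len(3) - 0.5) / n_bursts +
                                (u - 0.5) * 0.5 / n_bursts)
      widths <- stats::runif(3, 0.10, 0.18)
      amps <- stats::runif(3, 0.6, 1.1)
      baseline <- stats::runif(1, 0.45, 0.60)
      e <- burst_envelope(t, centres[seq_len(n_bursts)],
                          widths[seq_len(n_bursts)], amps[seq_len(n_bursts)],
                          baseline)
      r <- mean(e^4) / mean(e^2)^2
      beta <- ggd_shape_for_kurtosis((target + 3) / r - 3)
      # carrier uniforms come from a fixed-size budget independent of the
      # cycle duration, so trials of different conditions share the same
      # underlying draws at a given seed (the qgamma transform is then
      # pointwise monotone in the shape, which keeps the pooled kurtosis
      # ordered across conditions)
      n_draw <- max(n, ceiling(1.25 * fs))
      u <- stats::runif(2 * n_draw)
      sgn <- ifelse(u[seq_len(n)] < 0.5, -1, 1)
      carrier <- sgn * stats::qgamma(u[n_draw + seq_len(n)],
                                     shape = 1 / beta, rate = 1)^(1 / beta)
      s <- carrier * e
      s / sqrt(mean(s^2))
    })
  }
  labels <- sprintf("ch%02d", seq_len(n_channels))
  rownames(sig) <- labels
  structure(list(signal = sig, fs = fs, events = c(1L, n),
                 channel_labels = labels, condition = cond$label,
                 seed = as.integer(seed)),
            class = "emg_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("Raw EMG trial: %d channels x %d samples @ %g Hz (%s, seed %d)\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$condition, x$seed))
  invisible(x)
}

#' Simulate an activation matrix with known synergy structure
#'
#' Builds a ground-truth synergy model `x = w h + e`: non-negative muscle
#' weights `w_true` (each synergy dominated by a distinct muscle group),
#' smooth unimodal/bimodal non-negative excitation primitives `h_true`
#' (peak-normalised rows), additive Gaussian noise clipped at zero, and a
#' final per-muscle peak normalisation so the output obeys the activation
#' matrix contract (values in \[0, 1\], each non-zero row peaking at 1).
#'
#' The synergy bursts are temporally separated and the muscle groups are
#' close to balanced, so the `k_true` components each carry a substantial
#' share of signal energy; this makes the number of synergies identifiable
#' by the variance-accounted-for criterion.
#'
#' @param n_muscles Number of muscles L (rows).
#' @param k_true Number of ground-truth synergies (must be `< n_muscles`).
#' @param n_points Number of time points per gait cycle (default 200).
#' @param noise_sd Standard deviation of the additive Gaussian noise before
#'   clipping at zero.
#' @param seed Optional integer seed.
#' @return An object of class `synergy_sim`: list with `x` (the activation
#'   matrix), `w_true`, `h_true`, `noise_sd`, `seed`.
#' @examples
#' sim <- simulate_synergy_dataset(seed = 3)
#' range(sim$x)
#' @export
simulate_synergy_dataset <- function(n_muscles = 10, k_true = 3,
                                     n_points = 200, noise_sd = 0.05,
                                     seed = NULL) {
  if (k_true >= n_muscles)
    stop_invalid("'k_true' must be smaller than 'n_muscles'")
  if (k_true < 1 || n_points < 2) stop_invalid("invalid dimensions")
  if (noise_sd < 0) stop_invalid("'noise_sd' must be non-negative")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)

  res <- with_seed(seed, {
    t <- (seq_len(n_points) - 1) / (n_points - 1)
    h <- matrix(0, k_true, n_points)
    for (k in seq_len(k_true)) {
      centre <- (k - 0.5) / k_true + stats::runif(1, -0.04, 0.04)
      width <- stats::runif(1, 0.05, 0.09)
      row <- exp(-(t - centre)^2 / (2 * width^2))
      if (stats::runif(1) < 0.3) {
        c2 <- stats::runif(1, 0.05, 0.95)
        row <- row + stats::runif(1, 0.2, 0.5) *
          exp(-(t - c2)^2 / (2 * stats::runif(1, 0.05, 0.09)^2))
      }
      h[k, ] <- row / max(row)
    }
    groups <- rep(seq_len(k_true), length.out = n_muscles)
    w <- matrix(stats::runif(n_muscles * k_true, 0, 0.2), n_muscles, k_true)
    for (k in seq_len(k_true)) {
      idx <- which(groups == k)
      w[idx, k] <- w[idx, k] + stats::runif(length(idx), 0.8, 1.2)
    }
    x <- w %*% h
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(n_muscles * n_points, 0, noise_sd),
                      n_muscles, n_points)
    x <- pmax(x, 0)
    peaks <- apply(x, 1, max)
    scale <- ifelse(peaks > 0, 1 / peaks, 1)
    list(x = x * scale, w = w, h = h)
  })
  rownames(res$x) <- sprintf("m%02d", seq_len(n_muscles))
  structure(list(x = res$x, w_true = res$w, h_true = res$h,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synergy_sim")
}

#' @export
print.synergy_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic synergy dataset: %d muscles x %d points, k_true = %d, noise sd %.3g (seed %d)\n",
    nrow(x$x), ncol(x$x), nrow(x$h_true), x$noise_sd, x$seed))
  invisible(x)
}
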