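# EMG preprocessing: band-pass, rectification + linear envelope, and
# amplitude/time normalisation to the gait cycle.

# Steady-state initial conditions for a direct-form-II-transposed IIR
# filter, i.e. the state that makes the step response start at its
# asymptote. Used so forward-backward filtering has no startup transient on
# the (reflected) padding.
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1]
  b <- c(b, rep(0, n - length(b))) / 1
  if (n == 1) return(numeric(0))
  # companion matrix of a
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  rhs <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), rhs)
}

# Direct-form-II-transposed filtering with initial state zi.
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  y <- numeric(length(x))
  z <- zi
  bt <- b[-1]; at <- a[-1]
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    z <- c(z[-1], 0) + bt * x[i] - at * y[i]
  }
  y
}

#' Zero-lag (forward-backward) IIR filtering
#'
#' Applies the filter forwards then backwards so the net phase response is
#' zero and the magnitude response is squared. Edges are handled by
#' odd-reflection padding (3 x the coefficient length, capped at the signal
#' length minus one) with steady-state initial conditions scaled to the
#' first padded sample, the standard zero-phase recipe.
#'
#' @param b,a Numerator and denominator filter coefficients.
#' @param x Numeric vector to filter.
#' @return Filtered vector, same length as `x`.
#' @keywords internal
#' @export
filtfilt_zero_lag <- function(b, a, x) {
  nx <- length(x)
  if (nx < 4) stop_invalid("signal too short to filter")
  padlen <- min(3L * max(length(a), length(b)), nx - 1L)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[nx] - x[(nx - 1):(nx - padlen)])
  zi <- iir_steady_state(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + nx)]
}

#' Band-pass filter raw EMG
#'
#' Zero-lag Butterworth band-pass, applied per channel. The default
#' 30--400 Hz band with a 4th-order design (8-pole band-pass, order doubled
#' again by the forward-backward pass) is the conventional surface-EMG
#' conditioning band: it removes movement artefact and baseline drift below
#' 30 Hz and out-of-band noise above 400 Hz.
#'
#' @param x Channels x samples numeric matrix (or a single numeric vector).
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth design order (per band edge).
#' @return Filtered matrix of the same shape.
#' @export
emg_bandpass <- function(x, fs, low = 30, high = 400, order = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  check_matrix(x)
  if (!(low > 0 && low < high && high < fs / 2))
    stop_invalid("require 0 < low < high < fs/2 (got low=%g, high=%g, fs=%g)",
                 low, high, fs)
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(x, 1, function(row) filtfilt_zero_lag(flt$b, flt$a, row)))
  dimnames(out) <- dimnames(x)
  if (vec) out[1, ] else out
}

#' Linear envelope of an EMG signal
#'
#' Full-wave rectification followed by a zero-lag 4th-order Butterworth
#' low-pass (default cut-off 6 Hz), the classical EMG linear envelope.
#' Small negative excursions from filter ringing are clipped at zero.
#'
#' @param x Channels x samples numeric matrix (or a vector).
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass cut-off in Hz (6 by default; 8 or 10 Hz are common
#'   alternatives and leave the envelope's amplitude distribution
#'   essentially unchanged).
#' @param order Butterworth design order.
#' @return Non-negative envelope matrix of the same shape.
#' @export
emg_envelope <- function(x, fs, cutoff = 6, order = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  check_matrix(x)
  if (!(cutoff > 0 && cutoff < fs / 2))
    stop_invalid("require 0 < cutoff < fs/2")
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- t(apply(abs(x), 1, function(row) filtfilt_zero_lag(flt$b, flt$a, row)))
  out <- pmax(out, 0)
  dimnames(out) <- dimnames(x)
  if (vec) out[1, ] else out
}

#' Amplitude- and time-normalise an envelope to the gait cycle
#'
#' Crops each channel to the gait-event window, resamples it to `n_points`
#' by linear interpolation on a uniform normalised-time grid, and divides
#' each channel by its own post-crop peak so every non-zero muscle pattern
#' spans \[0, 1\]. Identically-zero channels (dead electrodes) are left as
#' zeros with a message rather than an error.
#'
#' @param x Channels x samples envelope matrix.
#' @param events Integer pair `(start_sample, end_sample)`; must span at
#'   least 2 samples.
#' @param n_points Number of output time points (default 200).
#' @return Channels x `n_points` activation matrix with per-row peak 1.
#' @export
normalise_cycle <- function(x, events, n_points = 200) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  check_matrix(x)
  events <- as.integer(events)
  if (length(events) != 2L || events[1] < 1 || events[2] > ncol(x) ||
      events[2] - events[1] < 1)
    stop_invalid("'events' must span at least 2 samples within the trial")
  if (n_points < 2) stop_invalid("'n_points' must be at least 2")
  idx <- events[1]:events[2]
  src <- seq(0, 1, length.out = length(idx))
  dst <- seq(0, 1, length.out = n_points)
  out <- t(apply(x[, idx, drop = FALSE], 1, function(row)
    stats::approx(src, row, xout = dst)$y))
  peaks <- apply(out, 1, max)
  dead <- peaks <= 0
  if (any(dead))
    message(sprintf("%d channel(s) identically zero; left as zeros",
                    sum(dead)))
  out <- out * ifelse(dead, 1, 1 / pmax(peaks, .Machine$double.eps))
  rownames(out) <- rownames(x)
  if (vec) out[1, ] else out
}

#' Preprocess a raw EMG trial into an activation matrix
#'
#' The full conditioning chain: band-pass (30--400 Hz), full-wave
#' rectification, low-pass linear envelope (6 Hz), crop to the gait-event
#' window, time-normalise to `n_points` samples of the cycle and
#' amplitude-normalise each muscle to its trial peak. The result is the
#' L x `n_points` activation matrix factorised by [synergy()].
#'
#' @param trial An `emg_trial` (from [simulate_emg_trial()] or
#'   [read_emg_trial()]), or a channels x samples matrix if `fs` and
#'   `events` are given.
#' @param bandpass_low,bandpass_high Band-pass edges in Hz.
#' @param envelope_cutoff Envelope low-pass cut-off in Hz.
#' @param n_points Output time points per cycle.
#' @param fs,events Required when `trial` is a bare matrix.
#' @return Activation matrix (channels x `n_points`, values in \[0, 1\],
#'   each non-zero row peaking at 1).
#' @examples
#' tr <- simulate_emg_trial("walk", seed = 1)
#' x <- preprocess_trial(tr)
#' dim(x)
#' @export
preprocess_trial <- function(trial, bandpass_low = 30, bandpass_high = 400,
                             envelope_cutoff = 6, n_points = 200,
                             fs = NULL, events = NULL) {
  if (inherits(trial, "emg_trial")) {
    sig <- trial$signal; fs <- trial$fs; events <- trial$events
  } else {
    sig <- trial
    if (is.null(fs) || is.null(events))
      stop_invalid("'fs' and 'events' are required for a bare matrix")
  }
  bp <- emg_bandpass(sig, fs, bandpass_low, bandpass_high)
  env <- emg_envelope(bp, fs, envelope_cutoff)
  normalise_cycle(env, events, n_points)
}
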