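# Independent oracles used to cross-check package computations. These stay
# deliberately naive (dense grids, double loops, exhaustive permutations).

# Brute-force two-sample KS statistic: evaluate both ECDFs on a dense grid
# spanning the pooled range (plus the sample points themselves, where the
# step functions jump).
ks_brute <- function(a, b, ngrid = 1e5) {
  grid <- c(seq(min(a, b) - 1, max(a, b) + 1, length.out = ngrid), a, b)
  fa <- stats::ecdf(a)
  fb <- stats::ecdf(b)
  max(abs(fa(grid) - fb(grid)))
}

# Elementwise double-loop VAF
vaf_loop <- function(x, x_hat) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    num <- num + (x[i, j] - x_hat[i, j])^2
    den <- den + x[i, j]^2
  }
  1 - num / den
}

mse_loop <- function(x, x_hat) {
  s <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    s <- s + (x[i, j] - x_hat[i, j])^2
  s / length(x)
}

# Exhaustive permutation alignment on cosine similarity (feasible for small K)
exhaustive_match <- function(w_est, w_ref) {
  K <- ncol(w_ref)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (p in perms(seq_len(K))) {
    m <- mean(vapply(seq_len(K), function(j)
      cosine(w_est[, p[j]], w_ref[, j]), numeric(1)))
    if (m > best) best <- m
  }
  best
}

# Moving-RMS envelope oracle (window in seconds)
moving_rms <- function(x, fs, window = 0.167) {
  half <- max(1L, round(window * fs / 2))
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    sqrt(mean(x[idx]^2))
  }, numeric(1))
}
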