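# Probability-distribution machinery: moment summaries, Gaussian PDF model,
# empirical CDFs, the two-sample Kolmogorov-Smirnov dissimilarity and the
# muscle-vs-primitive comparison table.

#' Moment summary of a sample's amplitude distribution
#'
#' Population-moment estimators of mean, standard deviation, skewness and
#' excess kurtosis (Fisher convention: Gaussian = 0, Laplacian = 3). These
#' are the summaries used to characterise EMG amplitude distributions
#' across gait speeds and to parameterise the Gaussian PDF model.
#'
#' @param x Numeric vector with at least 4 observations.
#' @return List of class `dist_summary` with `mean`, `sd`, `skewness`,
#'   `excess_kurtosis`, `n`.
#' @examples
#' dist_summary(rnorm(1000))
#' @export
dist_summary <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop_invalid("sample contains missing values")
  n <- length(x)
  if (n < 4) stop_invalid("at least 4 observations required for kurtosis")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0)
    structure(list(mean = m, sd = 0, skewness = 0, excess_kurtosis = 0,
                   n = n), class = "dist_summary")
  else
    structure(list(mean = m, sd = sqrt(m2), skewness = m3 / m2^1.5,
                   excess_kurtosis = m4 / m2^2 - 3, n = n),
              class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d: mean %.4g, sd %.4g, skewness %.4g, excess kurtosis %.4g\n",
    x$n, x$mean, x$sd, x$skewness, x$excess_kurtosis))
  invisible(x)
}

#' Gaussian probability-density model of a sample
#'
#' Evaluates the Gaussian density with the sample's mean and standard
#' deviation on a grid -- the parametric PDF model used for visual
#' comparison of amplitude distributions.
#'
#' @param summary A `dist_summary` (or any list with `mean` and `sd`).
#' @param grid Numeric vector of evaluation points.
#' @return Density values on `grid`.
#' @export
gaussian_pdf_model <- function(summary, grid) {
  if (is.null(summary$sd) || summary$sd <= 0)
    stop_invalid("'sd' must be positive")
  stats::dnorm(grid, mean = summary$mean, sd = summary$sd)
}

#' Empirical cumulative distribution function of a sample
#'
#' The standard right-continuous ECDF assigning mass `1/n` to each
#' observation.
#'
#' @param x Non-empty numeric vector.
#' @return Object of class `ecdf_sample`: list with sorted `values`, `n`,
#'   and `fun` (a step function, callable as `e$fun(t)`).
#' @examples
#' e <- ecdf_sample(c(1, 2, 3))
#' e$fun(2)   # 2/3
#' @export
ecdf_sample <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || anyNA(x)) stop_invalid("non-empty numeric sample required")
  v <- sort(x)
  n <- length(v)
  structure(list(values = v, n = n,
                 fun = function(t) findInterval(t, v) / n),
            class = "ecdf_sample")
}

# Kolmogorov asymptotic survival function Q(lambda) = 2 sum (-1)^{j-1}
# exp(-2 j^2 lambda^2); returns the asymptotic two-sided p-value.
ks_p_value <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov dissimilarity
#'
#' Computes `D = sup |F_a - F_b|`, the maximum vertical distance between
#' the two empirical CDFs, by exact evaluation at the pooled sample points
#' (where both step functions jump), together with the asymptotic two-sided
#' p-value using the effective sample size `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric samples or `ecdf_sample` objects.
#' @return List with `statistic` (D, in \[0, 1\]), `p.value`, `n_a`, `n_b`.
#' @examples
#' ks_two_sample(rnorm(100), rnorm(100))$statistic
#' @export
ks_two_sample <- function(a, b) {
  va <- if (inherits(a, "ecdf_sample")) a$values else sort(as.numeric(a))
  vb <- if (inherits(b, "ecdf_sample")) b$values else sort(as.numeric(b))
  na <- length(va); nb <- length(vb)
  if (na == 0 || nb == 0) stop_invalid("both samples must be non-empty")
  pooled <- sort(unique(c(va, vb)))
  d <- max(abs(findInterval(pooled, va) / na - findInterval(pooled, vb) / nb))
  n_eff <- na * nb / (na + nb)
  list(statistic = d, p.value = ks_p_value(sqrt(n_eff) * d),
       n_a = na, n_b = nb)
}

#' Compare excitation-primitive and muscle-activation distributions
#'
#' For every pair of muscle activation pattern (row of `x`) and excitation
#' primitive (row of `h`), computes the two-sample KS dissimilarity `D` and
#' its p-value. Because the number of synergies K is always smaller than
#' the number of muscles L, each primitive is compared against all L
#' muscle patterns; `d_k` is the worst (largest) dissimilarity of primitive
#' k over muscles, and `d_max` -- the maximum dissimilarity index -- is the
#' single worst case over all pairs. The occurrence of agreement is the
#' percentage of the L x K pairs for which the KS test fails to reject
#' distribution equality at level `alpha`.
#'
#' Activations live in \[0, 1\] while primitives of the centring methods do
#' not, and the two-sample KS statistic is not invariant to rescaling one
#' sample only; by default each primitive is therefore min-max normalised
#' to \[0, 1\] before comparison (`normalise = "raw"` disables this for
#' sensitivity analysis).
#'
#' @param x Activation matrix (L x N).
#' @param fit A fitted `synergy` object, or a K x N primitive matrix.
#' @param alpha Significance level of the KS test (default 0.05).
#' @param normalise `"minmax"` (default) or `"raw"`.
#' @return Object of class `ks_comparison`: list with `d` and `p`
#'   (L x K matrices), `d_k` (per-primitive maxima), `d_max`,
#'   `agreement_pct` (in \[0, 100\]), `alpha`, `method`.
#' @examples
#' sim <- simulate_synergy_dataset(seed = 3)
#' fit <- synergy(sim$x, "nmf", k = 3, seed = 1)
#' ks_compare(sim$x, fit)
#' @export
ks_compare <- function(x, fit, alpha = 0.05,
                       normalise = c("minmax", "raw")) {
  normalise <- match.arg(normalise)
  check_matrix(x)
  h <- if (inherits(fit, "synergy")) fit$h else fit
  check_matrix(h, "primitives")
  L <- nrow(x); K <- nrow(h)
  if (K >= L)
    stop_invalid("number of synergies (%d) must be less than muscles (%d)",
                 K, L)
  d <- p <- matrix(NA_real_, L, K,
                   dimnames = list(rownames(x), sprintf("h%d", seq_len(K))))
  for (k in seq_len(K)) {
    hk <- h[k, ]
    if (normalise == "minmax") {
      rng <- range(hk)
      hk <- if (diff(rng) > 0) (hk - rng[1]) / diff(rng) else hk * 0
    }
    ek <- ecdf_sample(hk)
    for (l in seq_len(L)) {
      ks <- ks_two_sample(x[l, ], ek)
      d[l, k] <- ks$statistic
      p[l, k] <- ks$p.value
    }
  }
  structure(list(d = d, p = p, d_k = apply(d, 2, max), d_max = max(d),
                 agreement_pct = 100 * mean(p >= alpha), alpha = alpha,
                 method = if (inherits(fit, "synergy")) fit$method else NA),
            class = "ks_comparison")
}

#' @describeIn ks_compare long-format table (one row per muscle-primitive
#'   pair with `muscle`, `primitive`, `d`, `p`, `agrees`), convenient for
#'   CSV export and plotting.
#' @param row.names,optional,... Passed on for S3 compatibility (unused).
#' @export
as.data.frame.ks_comparison <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  L <- nrow(x$d); K <- ncol(x$d)
  data.frame(method = rep(x$method, L * K),
             muscle = rep(rownames(x$d) %||% seq_len(L), K),
             primitive = rep(seq_len(K), each = L),
             d = as.vector(x$d), p = as.vector(x$p),
             agrees = as.vector(x$p >= x$alpha),
             stringsAsFactors = FALSE)
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf(
    "KS comparison (%d muscles x %d primitives%s):\n", nrow(x$d), ncol(x$d),
    if (is.na(x$method)) "" else paste0(", ", toupper(x$method))))
  cat(sprintf("  maximum dissimilarity D = %.4f\n", x$d_max))
  cat(sprintf("  occurrence of agreement = %.1f%% (alpha = %g)\n",
              x$agreement_pct, x$alpha))
  invisible(x)
}
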