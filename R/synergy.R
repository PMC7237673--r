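#' Extract muscle synergies from an activation matrix
#'
#' Fits the linear synergy model `x = w h + e`, where `x` is the L x N
#' matrix of muscle activation patterns (L muscles, N time points of the
#' normalised gait cycle), `w` is the L x K matrix of time-independent
#' synergy weights and `h` the K x N matrix of time-varying excitation
#' primitives, with one of four factorisation methods:
#'
#' * `"nmf"` -- non-negative matrix factorisation by Lee-Seung
#'   multiplicative updates minimising the squared Frobenius (Euclidean)
#'   distance, with `w, h >= 0`. Non-convex, so multiple random restarts
#'   are run and the best final objective kept.
#' * `"pca"` -- principal component analysis via singular value
#'   decomposition of the per-muscle-centred data; primitives are mutually
#'   orthogonal and the reconstruction is the Eckart-Young optimum.
#' * `"ica"` -- independent component analysis: per-muscle centring,
#'   pre-whitening to K dimensions, then a fixed-point iteration maximising
#'   the absolute fourth moment (kurtosis contrast) with symmetric
#'   decorrelation. The K x K rotation is stored in `mixing`.
#' * `"fa"` -- factor analysis by principal-axis factoring of the muscle
#'   covariance matrix: loadings are the top-K eigenvectors scaled by the
#'   square root of their eigenvalues, factor scores by the regression
#'   method; no rotation.
#'
#' For the sign-indeterminate methods (PCA/ICA/FA) each primitive is
#' flipped so its skewness is non-negative (activation bursts are
#' right-skewed); exact ties are broken by making the largest-magnitude
#' weight positive. All methods then share a common output convention:
#' every primitive row is scaled to peak (absolute) value 1 with the
#' compensating scale folded into the weights, which leaves the
#' reconstruction unchanged.
#'
#' @param x Activation matrix (muscles x time, non-negative; NMF requires
#'   non-negativity, the other methods merely expect it).
#' @param method One of `"nmf"`, `"pca"`, `"ica"`, `"fa"`.
#' @param k Number of synergies, `1 <= k <= nrow(x)`.
#' @param seed Optional integer seed (used by NMF restarts and the ICA
#'   initial rotation; PCA and FA are deterministic).
#' @param max_iter,tol Iteration cap and relative convergence tolerance for
#'   the iterative methods (NMF default 1000 / 1e-6; ICA default 500 /
#'   1e-6).
#' @param restarts Number of random restarts for NMF (default 10).
#' @param contrast ICA contrast function: `"kurtosis"` (default, plain
#'   fourth moment) or `"logcosh"`.
#' @return An object of class `c("synergy_<method>", "synergy")`: a list
#'   with `w` (L x K weights), `h` (K x N primitives, rows peaking at 1),
#'   `offset` (per-muscle mean re-added on reconstruction; zeros for NMF),
#'   `mixing` (ICA rotation or `NULL`), `x`, `x_hat`, `vaf`, `method`, `k`,
#'   and for iterative methods `objective` (per-iteration trace),
#'   `iterations` and `converged`.
#' @examples
#' sim <- simulate_synergy_dataset(noise_sd = 0, seed = 3)
#' fit <- synergy(sim$x, "nmf", k = 3, seed = 1)
#' fit
#' round(vaf(sim$x, fitted(fit)), 4)
#' @seealso [vaf()], [ks_compare()], [select_synergy_count()]
#' @export
synergy <- function(x, method = c("nmf", "pca", "ica", "fa"), k,
                    seed = NULL, max_iter = NULL, tol = 1e-6,
                    restarts = 10, contrast = c("kurtosis", "logcosh")) {
  method <- match.arg(method)
  check_matrix(x)
  L <- nrow(x); N <- ncol(x)
  if (length(k) != 1L || k < 1 || k > L)
    stop_invalid("'k' must be between 1 and the number of muscles (%d)", L)
  k <- as.integer(k)

  fit <- switch(method,
    nmf = .fit_nmf(x, k, seed, max_iter %||% 1000L, tol, restarts),
    pca = .fit_pca(x, k),
    ica = .fit_ica(x, k, seed, max_iter %||% 500L, tol, match.arg(contrast)),
    fa  = .fit_fa(x, k))

  if (method != "nmf") fit <- .fix_signs(fit)
  fit <- .normalise_primitives(fit)
  x_hat <- fit$w %*% fit$h + (fit$offset %||% 0)
  dimnames(x_hat) <- dimnames(x)
  rownames(fit$w) <- rownames(x)
  obj <- structure(
    c(list(x = x, x_hat = x_hat, method = method, k = k,
           vaf = vaf(x, x_hat), channel_labels = rownames(x),
           call = match.call()),
      fit),
    class = c(paste0("synergy_", method), "synergy"))
  obj
}

# ---- method internals -----------------------------------------------------

.fit_nmf <- function(x, k, seed, max_iter, tol, restarts, eps = 1e-12) {
  if (any(x < 0)) stop_invalid("NMF requires a non-negative matrix")
  L <- nrow(x); N <- ncol(x)
  best <- NULL
  init_scale <- sqrt(mean(x) / k)
  for (r in seq_len(restarts)) {
    rs <- if (is.null(seed)) NULL else derive_seed(seed, r)
    run <- with_seed(rs, {
      w <- matrix(stats::runif(L * k), L, k) * init_scale
      h <- matrix(stats::runif(k * N), k, N) * init_scale
      trace <- numeric(max_iter)
      conv <- FALSE
      it <- 0L
      prev <- Inf
      while (it < max_iter) {
        it <- it + 1L
        h <- h * (crossprod(w, x)) / (crossprod(w, w) %*% h + eps)
        w <- w * (x %*% t(h)) / (w %*% tcrossprod(h, h) + eps)
        obj <- sum((x - w %*% h)^2)
        trace[it] <- obj
        if (is.finite(prev) && (prev - obj) <= tol * max(prev, eps)) {
          conv <- TRUE
          break
        }
        prev <- obj
      }
      list(w = w, h = h, objective = trace[seq_len(it)], iterations = it,
           converged = conv)
    })
    if (is.null(best) ||
        utils::tail(run$objective, 1) < utils::tail(best$objective, 1))
      best <- run
  }
  best$offset <- rep(0, L)
  best
}

.fit_pca <- function(x, k) {
  offset <- rowMeans(x)
  xc <- x - offset
  sv <- svd(xc)
  w <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  h <- t(sv$v[, seq_len(k), drop = FALSE])
  list(w = w, h = h, offset = offset, singular_values = sv$d)
}

.fit_ica <- function(x, k, seed, max_iter, tol, contrast) {
  L <- nrow(x); N <- ncol(x)
  offset <- rowMeans(x)
  xc <- x - offset
  C <- tcrossprod(xc) / N
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(k)], 1e-12)
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  whiten <- diag(1 / sqrt(lam), k) %*% t(E)      # k x L
  dewhiten <- E %*% diag(sqrt(lam), k)           # L x k
  z <- whiten %*% xc                             # k x N, unit covariance

  rot <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  })
  sym_decorrelate <- function(m) {
    e <- eigen(tcrossprod(m), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% m
  }
  rot <- sym_decorrelate(rot)
  converged <- FALSE
  it <- 0L
  # stabilized fixed point: start with the plain update and halve the step
  # when the iteration oscillates (the symmetric cubic-contrast update can
  # enter a 2-cycle on near-degenerate data)
  mu <- 1
  best_delta <- Inf
  stall <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- rot %*% z
    upd <- if (contrast == "kurtosis") {
      (s^3 %*% t(z)) / N - 3 * rot
    } else {
      g <- tanh(s)
      (g %*% t(z)) / N - diag(rowMeans(1 - g^2), k) %*% rot
    }
    new <- sym_decorrelate(mu * upd + (1 - mu) * rot)
    delta <- max(abs(1 - abs(rowSums(new * rot))))
    rot <- new
    if (delta < tol) { converged <- TRUE; break }
    if (delta < best_delta * 0.9) { best_delta <- delta; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= 10L && mu > 0.124) { mu <- mu / 2; stall <- 0L }
  }
  if (!converged)
    warning(sprintf("ICA did not converge in %d iterations; returning best effort",
                    max_iter))
  h <- rot %*% z
  w <- dewhiten %*% t(rot)
  list(w = w, h = h, offset = offset, mixing = rot, iterations = it,
       converged = converged)
}

.fit_fa <- function(x, k, eig_floor = 1e-12) {
  L <- nrow(x); N <- ncol(x)
  offset <- rowMeans(x)
  xc <- x - offset
  C <- tcrossprod(xc) / N
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, eig_floor)
  loadings <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  Cinv <- eg$vectors %*% diag(1 / lam, L) %*% t(eg$vectors)
  scores <- t(loadings) %*% Cinv %*% xc
  list(w = loadings, h = scores, offset = offset, eigenvalues = eg$values)
}

# flip each primitive so its skewness is >= 0; break exact ties by making
# the largest-magnitude weight positive (needed because ECDF comparison of
# primitives is not sign-invariant)
.fix_signs <- function(fit) {
  for (i in seq_len(nrow(fit$h))) {
    row <- fit$h[i, ]
    m <- mean(row)
    s2 <- mean((row - m)^2)
    sk <- if (s2 > 0) mean((row - m)^3) / s2^1.5 else 0
    flip <- if (abs(sk) > 1e-12) sk < 0 else {
      fit$w[which.max(abs(fit$w[, i])), i] < 0
    }
    if (flip) {
      fit$h[i, ] <- -fit$h[i, ]
      fit$w[, i] <- -fit$w[, i]
      if (!is.null(fit$mixing)) fit$mixing[i, ] <- -fit$mixing[i, ]
    }
  }
  fit
}

# common output convention: each primitive row peaks at (absolute) 1, with
# the compensating scale folded into the weights; reconstruction invariant
.normalise_primitives <- function(fit) {
  sc <- apply(abs(fit$h), 1, max)
  sc[sc <= 0] <- 1
  fit$h <- fit$h / sc
  fit$w <- fit$w * rep(sc, each = nrow(fit$w))
  fit
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.synergy <- function(x, ...) {
  cat(sprintf("Muscle synergy decomposition (%s), K = %d\n",
              toupper(x$method), x$k))
  cat(sprintf("  %d muscles x %d time points; VAF = %.4f\n",
              nrow(x$x), ncol(x$x), x$vaf))
  if (!is.null(x$iterations))
    cat(sprintf("  %d iterations%s\n", x$iterations,
                if (isFALSE(x$converged)) " (not converged)" else ""))
  invisible(x)
}

#' @export
summary.synergy <- function(object, ...) {
  st <- reconstruction_error_stats(object$x, object)
  out <- list(method = object$method, k = object$k, vaf = object$vaf,
              stats = st, dims = dim(object$x),
              weight_totals = colSums(object$w))
  class(out) <- "summary.synergy"
  out
}

#' @export
print.summary.synergy <- function(x, ...) {
  cat(sprintf("Synergy decomposition: %s, K = %d (%d muscles x %d points)\n",
              toupper(x$method), x$k, x$dims[1], x$dims[2]))
  cat(sprintf("  VAF                 %.4f\n", x$vaf))
  cat(sprintf("  MSE                 %.3e\n", x$stats$mse))
  cat(sprintf("  var(reconstruction) %.3e\n", x$stats$var_xhat))
  cat(sprintf("  residual variance   %.3e\n", x$stats$var_e))
  cat("  total weight per synergy:",
      paste(sprintf("%.2f", x$weight_totals), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.synergy <- function(object, ...) object$w

#' @export
fitted.synergy <- function(object, ...) object$x_hat

#' @export
residuals.synergy <- function(object, ...) object$x - object$x_hat

#' Rebuild the activation matrix from a decomposition
#'
#' Recomputes `w h` (plus the per-muscle offset for the centring methods)
#' from the stored factors. Pure and idempotent; equal to [fitted()] up to
#' floating-point reassembly.
#'
#' @param object A fitted `synergy` object.
#' @return L x N reconstruction matrix.
#' @export
reconstruct <- function(object) {
  stopifnot(inherits(object, "synergy"))
  if (ncol(object$w) != nrow(object$h))
    stop_invalid("inconsistent decomposition shapes")
  object$w %*% object$h + (object$offset %||% 0)
}

#' Reconstruction-error diagnostics
#'
#' Returns the mean squared error between `x` and the reconstruction, the
#' variance of the reconstruction and the residual variance. Under the
#' modelling assumption that the residual is zero-mean Gaussian and
#' independent of the reconstruction, the MSE decomposes (up to the
#' residual's mean and the reconstruction bias) into reconstruction
#' variance plus residual variance; the three numbers are reported as a
#' diagnostic of that decomposition.
#'
#' @param x Activation matrix.
#' @param object A fitted `synergy` object or a reconstruction matrix.
#' @return List with `mse`, `var_xhat`, `var_e`.
#' @export
reconstruction_error_stats <- function(x, object) {
  x_hat <- if (inherits(object, "synergy")) object$x_hat else object
  check_matrix(x); check_matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) stop_invalid("shape mismatch")
  e <- x - x_hat
  list(mse = mean(e^2),
       var_xhat = mean((x_hat - mean(x_hat))^2),
       var_e = mean((e - mean(e))^2))
}

#' @export
plot.synergy <- function(x, ...) {
  k <- x$k
  op <- graphics::par(mfrow = c(k, 2), mar = c(2.5, 3.5, 1.5, 0.5),
                      mgp = c(2, 0.6, 0))
  on.exit(graphics::par(op))
  labels <- x$channel_labels %||% sprintf("m%d", seq_len(nrow(x$w)))
  tgrid <- seq(0, 100, length.out = ncol(x$h))
  for (i in seq_len(k)) {
    graphics::barplot(x$w[, i], names.arg = labels, las = 2,
                      cex.names = 0.6, ylab = sprintf("W%d", i),
                      main = if (i == 1) sprintf("%s weights", toupper(x$method)) else "")
    graphics::plot(tgrid, x$h[i, ], type = "l", lwd = 2,
                   xlab = "% gait cycle", ylab = sprintf("H%d", i),
                   main = if (i == 1) "excitation primitives" else "")
  }
  invisible(x)
}

#' Number of significant factors by the eigenvalue-greater-than-one rule
#'
#' Counts eigenvalues of the muscle correlation matrix (i.e. of the
#' standardised activation data) that exceed 1, the classical factor
#' analysis retention heuristic: components explaining less variance than a
#' single standardised muscle are treated as noise.
#'
#' @param x Activation matrix (muscles x time).
#' @return List with `k` (suggested number of synergies) and `eigenvalues`.
#' @export
fa_eigenvalue_rule <- function(x) {
  check_matrix(x)
  xs <- t(scale(t(x)))
  xs[is.na(xs)] <- 0                      # constant rows carry no signal
  C <- tcrossprod(xs) / (ncol(x) - 1)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  list(k = sum(ev > 1), eigenvalues = ev)
}
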