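# Variance accounted for, synergy-number selection, dataset scoring and
# group-level statistics.

#' Variance accounted for
#'
#' The global (uncentred) variance accounted for,
#' \deqn{\mathrm{VAF} = 1 - \sum_{l,t} (x_{lt} - \hat x_{lt})^2 /
#'   \sum_{l,t} x_{lt}^2,}
#' i.e. one minus residual energy over total signal energy -- the standard
#' reconstruction-quality metric of the synergy literature.
#'
#' @param x Activation matrix.
#' @param x_hat Reconstruction of the same shape (or a fitted `synergy`
#'   object).
#' @return Scalar VAF (at most 1; can be negative for reconstructions worse
#'   than zero).
#' @examples
#' x <- matrix(runif(20), 4)
#' vaf(x, x)        # 1
#' vaf(x, x * 0)    # 0
#' @export
vaf <- function(x, x_hat) {
  if (inherits(x_hat, "synergy")) x_hat <- x_hat$x_hat
  check_matrix(x); check_matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) stop_invalid("shape mismatch")
  denom <- sum(x^2)
  if (denom == 0) stop_invalid("VAF undefined for an all-zero matrix")
  1 - sum((x - x_hat)^2) / denom
}

#' Select the number of muscle synergies
#'
#' Returns the smallest K in `k_range` at which every requested
#' factorisation method attains VAF above `threshold` (default 85%), the
#' standard model-order criterion for synergy analysis. If no K in the
#' range satisfies the criterion the range maximum is returned with a
#' warning.
#'
#' @param x Activation matrix.
#' @param methods Character vector of factorisation methods to require.
#' @param k_range Candidate numbers of synergies (default `2:6`).
#' @param threshold VAF threshold as a fraction (default 0.85).
#' @param seed Optional integer seed for the stochastic methods.
#' @param ... Further arguments passed to [synergy()].
#' @return The selected K (integer) with attributes `vaf` (methods x K
#'   matrix of the VAF values computed) and `reached` (logical).
#' @examples
#' sim <- simulate_synergy_dataset(noise_sd = 0.02, seed = 3)
#' select_synergy_count(sim$x, seed = 1)
#' @export
select_synergy_count <- function(x, methods = c("nmf", "pca", "ica", "fa"),
                                 k_range = 2:6, threshold = 0.85,
                                 seed = NULL, ...) {
  if (length(methods) == 0) stop_invalid("'methods' must be non-empty")
  methods <- match.arg(methods, c("nmf", "pca", "ica", "fa"),
                       several.ok = TRUE)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > nrow(x))
    stop_invalid("'k_range' must lie within 1..%d", nrow(x))
  vaf_tab <- matrix(NA_real_, length(methods), length(k_range),
                    dimnames = list(methods, k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    for (m in methods) {
      fit <- synergy(x, m, k, seed = if (is.null(seed)) NULL
                     else derive_seed(seed, j * 101 + match(m, methods)), ...)
      vaf_tab[m, j] <- fit$vaf
    }
    if (all(vaf_tab[, j] > threshold)) {
      return(structure(k, vaf = vaf_tab[, seq_len(j), drop = FALSE],
                       reached = TRUE))
    }
  }
  warning(sprintf(
    "VAF threshold %.2f not reached by all methods for any K in %d..%d; returning %d",
    threshold, min(k_range), max(k_range), max(k_range)))
  structure(max(k_range), vaf = vaf_tab, reached = FALSE)
}

#' Score trials with every factorisation method
#'
#' For each trial and method: fit the decomposition at `k` synergies,
#' compute the VAF of the reconstruction, and compare primitive and
#' activation distributions ([ks_compare()]) to obtain the occurrence of
#' agreement and the maximum dissimilarity index. Per-trial failures are
#' reported as warnings and skipped rather than aborting the run.
#'
#' @param trials List of activation matrices (consistent muscle count).
#' @param methods Factorisation methods to score.
#' @param k Number of synergies (common to all methods, default 3).
#' @param seed Optional integer master seed; each trial x method fit gets a
#'   derived sub-seed, so results are reproducible bit-for-bit.
#' @param trial_info Optional data frame with one row per trial (e.g.
#'   columns `trial_id`, `subject`, `condition`) carried into the output.
#' @param alpha KS significance level.
#' @return Data frame with one row per trial x method: `trial_id`,
#'   `method`, `k`, `vaf`, `agreement_pct`, `d_max`, plus any `trial_info`
#'   columns.
#' @export
score_trials <- function(trials, methods = c("nmf", "pca", "ica", "fa"),
                         k = 3, seed = NULL, trial_info = NULL,
                         alpha = 0.05) {
  stopifnot(is.list(trials), length(trials) > 0)
  methods <- match.arg(methods, c("nmf", "pca", "ica", "fa"),
                       several.ok = TRUE)
  L <- nrow(trials[[1]])
  rows <- list()
  for (i in seq_along(trials)) {
    x <- trials[[i]]
    if (nrow(x) != L) stop_invalid("inconsistent muscle count across trials")
    for (m in methods) {
      res <- tryCatch({
        fit <- synergy(x, m, k,
                       seed = if (is.null(seed)) NULL
                       else derive_seed(seed, i * 17 + match(m, methods)))
        ks <- ks_compare(x, fit, alpha = alpha)
        data.frame(trial_id = i, method = m, k = k, vaf = fit$vaf,
                   agreement_pct = ks$agreement_pct, d_max = ks$d_max,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("trial %d, method %s failed: %s", i, m,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        if (!is.null(trial_info)) res <- cbind(res, trial_info[i, , drop = FALSE])
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated-measures comparison of factorisation methods
#'
#' One-way repeated-measures ANOVA of a score metric across methods, with
#' subjects as the repeated factor, followed by Bonferroni-corrected paired
#' t-tests for all method pairs. Trials are first aggregated to
#' subject-by-method means (subjects, not trials, are the repeated units);
#' the design must be balanced (every subject scored with every method).
#'
#' @param scores Data frame from [score_trials()] including a `subject`
#'   column.
#' @param metric Which score to compare: `"vaf"`, `"agreement_pct"` or
#'   `"d_max"`.
#' @return Object of class `method_comparison`: list with `anova`
#'   (`F`, `df1`, `df2`, `p`), `pairwise` (data frame with raw and
#'   Bonferroni-corrected p-values), `means`, `metric`, `n_subjects`.
#' @export
compare_methods <- function(scores, metric = c("vaf", "agreement_pct", "d_max")) {
  metric <- match.arg(metric)
  if (!all(c("method", "subject", metric) %in% names(scores)))
    stop_invalid("'scores' must have columns 'method', 'subject', '%s'", metric)
  agg <- stats::aggregate(scores[[metric]],
                          by = list(subject = scores$subject,
                                    method = scores$method), FUN = mean)
  names(agg)[3] <- "value"
  methods <- sort(unique(agg$method))
  subjects <- sort(unique(agg$subject))
  tab <- table(agg$subject, agg$method)
  if (any(tab != 1))
    stop_invalid(paste("unbalanced design: every subject must have scores",
                       "for every method (aggregate or complete the data first)"))
  if (length(methods) < 2 || length(subjects) < 2)
    stop_invalid("need at least 2 methods and 2 subjects")

  agg$subject <- factor(agg$subject)
  agg$method <- factor(agg$method)
  if (stats::var(agg$value) < 1e-24) {
    an <- list(F = 0, df1 = length(methods) - 1,
               df2 = (length(methods) - 1) * (length(subjects) - 1), p = 1)
  } else {
    fit <- stats::aov(value ~ method + Error(subject), data = agg)
    s <- summary(fit)[["Error: Within"]][[1]]
    an <- list(F = s["method", "F value"], df1 = s["method", "Df"],
               df2 = s["Residuals", "Df"], p = s["method", "Pr(>F)"])
  }

  pairs <- utils::combn(methods, 2)
  m <- ncol(pairs)
  pw <- data.frame(method_a = pairs[1, ], method_b = pairs[2, ],
                   estimate = NA_real_, p_raw = NA_real_,
                   p_bonferroni = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    sa <- agg[agg$method == pairs[1, j], ]
    sb <- agg[agg$method == pairs[2, j], ]
    va <- sa$value[match(subjects, sa$subject)]
    vb <- sb$value[match(subjects, sb$subject)]
    dif <- va - vb
    pw$estimate[j] <- mean(dif)
    pw$p_raw[j] <- if (stats::sd(dif) < 1e-15) {
      if (abs(mean(dif)) < 1e-15) 1 else 0
    } else stats::t.test(dif)$p.value
  }
  pw$p_bonferroni <- pmin(1, m * pw$p_raw)

  means <- tapply(agg$value, agg$method, mean)
  structure(list(anova = an, pairwise = pw, means = means, metric = metric,
                 n_subjects = length(subjects)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s (%d subjects):\n", x$metric,
              x$n_subjects))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$anova$df1, x$anova$df2,
              x$anova$F, x$anova$p))
  cat("  method means:",
      paste(sprintf("%s = %.4g", names(x$means), x$means), collapse = ", "),
      "\n  Bonferroni-corrected pairwise p-values:\n")
  for (j in seq_len(nrow(x$pairwise)))
    cat(sprintf("    %s vs %s: diff %.4g, p = %.4g\n",
                x$pairwise$method_a[j], x$pairwise$method_b[j],
                x$pairwise$estimate[j], x$pairwise$p_bonferroni[j]))
  invisible(x)
}

#' Match estimated synergy weights to a reference set
#'
#' Greedily pairs columns of `w_est` with columns of `w_ref` by cosine
#' similarity (largest first), resolving the permutation ambiguity of
#' factorisation so that recovered and ground-truth synergies can be
#' compared.
#'
#' @param w_est,w_ref L x K weight matrices.
#' @return List with `perm` (`perm[j]` is the column of `w_est` matched to
#'   column `j` of `w_ref`), `cosines` (per-pair similarity) and
#'   `mean_cosine`.
#' @export
match_synergies <- function(w_est, w_ref) {
  check_matrix(w_est); check_matrix(w_ref)
  if (!all(dim(w_est) == dim(w_ref))) stop_invalid("shape mismatch")
  K <- ncol(w_ref)
  norm_e <- sqrt(colSums(w_est^2)); norm_r <- sqrt(colSums(w_ref^2))
  sim <- crossprod(w_est, w_ref) /
    (pmax(norm_e, 1e-300) %o% pmax(norm_r, 1e-300))
  perm <- integer(K); cosines <- numeric(K)
  avail_e <- rep(TRUE, K); avail_r <- rep(TRUE, K)
  for (step in seq_len(K)) {
    masked <- sim
    masked[!avail_e, ] <- -Inf
    masked[, !avail_r] <- -Inf
    best <- which(masked == max(masked), arr.ind = TRUE)[1, ]
    perm[best[2]] <- best[1]
    cosines[best[2]] <- sim[best[1], best[2]]
    avail_e[best[1]] <- FALSE
    avail_r[best[2]] <- FALSE
  }
  list(perm = perm, cosines = cosines, mean_cosine = mean(cosines))
}
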