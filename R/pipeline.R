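# End-to-end reproducible runs: configuration, batch simulation, scoring and
# reporting.

#' Analysis configuration
#'
#' Assembles and validates the parameters of the full comparison pipeline.
#' Every value is checked against the preconditions of the operation that
#' consumes it at construction time, so a bad configuration fails before
#' any computation starts.
#'
#' @param bandpass_low_hz,bandpass_high_hz Band-pass edges (default 30/400).
#' @param envelope_cutoff_hz Linear-envelope low-pass cut-off (default 6).
#' @param n_points Time points per normalised gait cycle (default 200).
#' @param k Number of synergies for the comparison (default 3); use
#'   `"auto"` to select by the VAF criterion.
#' @param k_range Candidate K values for selection (default 2:6).
#' @param vaf_threshold VAF selection threshold as a fraction (default 0.85).
#' @param alpha KS significance level (default 0.05).
#' @param methods Factorisation methods to compare.
#' @param seed Master seed for all stochastic steps.
#' @param fs_hz Sampling rate for simulated trials (default 1500).
#' @return Validated list of class `synergy_config`.
#' @export
synergy_config <- function(bandpass_low_hz = 30, bandpass_high_hz = 400,
                           envelope_cutoff_hz = 6, n_points = 200,
                           k = 3, k_range = 2:6, vaf_threshold = 0.85,
                           alpha = 0.05,
                           methods = c("nmf", "pca", "ica", "fa"),
                           seed = 1, fs_hz = 1500) {
  cfg <- list(bandpass_low_hz = bandpass_low_hz,
              bandpass_high_hz = bandpass_high_hz,
              envelope_cutoff_hz = envelope_cutoff_hz,
              n_points = as.integer(n_points), k = k,
              k_range = as.integer(k_range),
              vaf_threshold = vaf_threshold, alpha = alpha,
              methods = match.arg(methods, c("nmf", "pca", "ica", "fa"),
                                  several.ok = TRUE),
              seed = as.integer(seed), fs_hz = fs_hz)
  if (!(cfg$bandpass_low_hz > 0 &&
        cfg$bandpass_low_hz < cfg$bandpass_high_hz &&
        cfg$bandpass_high_hz < cfg$fs_hz / 2))
    stop_invalid("invalid band-pass edges for fs = %g Hz", cfg$fs_hz)
  if (!(cfg$envelope_cutoff_hz > 0 && cfg$envelope_cutoff_hz < cfg$fs_hz / 2))
    stop_invalid("invalid envelope cut-off")
  if (cfg$n_points < 2) stop_invalid("'n_points' must be at least 2")
  if (!identical(cfg$k, "auto") && (cfg$k < 1))
    stop_invalid("'k' must be positive or \"auto\"")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop_invalid("'alpha' must be in (0,1)")
  if (!(cfg$vaf_threshold >= 0 && cfg$vaf_threshold <= 1))
    stop_invalid("'vaf_threshold' must be a fraction in [0,1]")
  class(cfg) <- "synergy_config"
  cfg
}

#' Read or write a configuration file
#'
#' JSON (always) or YAML (if the `yaml` package is installed), chosen by
#' file extension. Configurations round-trip without loss.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param config A `synergy_config`.
#' @return `read_config()` returns a validated `synergy_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synergy_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synergy_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("the 'yaml' package is required for YAML configs")
    yaml::write_yaml(x, path)
  } else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a batch of trials to disk
#'
#' Writes `n_subjects x n_trials` simulated raw-EMG trials per condition as
#' CSV + JSON pairs, together with a `manifest.json` recording every file,
#' its condition, subject, trial number and derived seed. Rerunning with
#' the same seed reproduces every file bit-for-bit.
#'
#' @param out_dir Output directory (created if missing).
#' @param conditions Condition labels to simulate.
#' @param n_subjects,n_trials Subjects per condition and trials per subject.
#' @param n_channels,fs Channels and sampling rate for [simulate_emg_trial()].
#' @param seed Master seed.
#' @return Invisibly, the manifest as a data frame.
#' @export
simulate_trials <- function(out_dir,
                            conditions = c("walk", "slow_run",
                                           "moderate_run", "fast_run"),
                            n_subjects = 2, n_trials = 3, n_channels = 10,
                            fs = 1500, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (n_trials < 1) warning("n_trials is zero; writing an empty manifest")
  rows <- list()
  idx <- 0L
  for (cond in conditions) for (s in seq_len(n_subjects))
    for (tr in seq_len(max(0L, n_trials))) {
      idx <- idx + 1L
      trial_seed <- derive_seed(seed, idx)
      trial <- simulate_emg_trial(cond, n_channels = n_channels, fs = fs,
                                  seed = trial_seed)
      prefix <- file.path(out_dir, sprintf("%s_sub%02d_trial%02d", cond, s, tr))
      write_emg_trial(trial, prefix)
      rows[[idx]] <- data.frame(file = basename(prefix), condition = cond,
                                subject = s, trial = tr, seed = trial_seed,
                                stringsAsFactors = FALSE)
    }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), condition = character(),
               subject = integer(), trial = integer(), seed = integer())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  message(sprintf("wrote %d trial(s) to %s (master seed %d)",
                  nrow(manifest), out_dir, seed))
  invisible(manifest)
}

#' Run the full factorisation-method comparison
#'
#' Reads every trial listed in the input directory's manifest, preprocesses
#' it to an activation matrix, fixes the number of synergies (either the
#' configured `k` or VAF-based selection on the first trial of each
#' condition), scores every trial with every method ([score_trials()]), and
#' runs the repeated-measures comparison per condition and metric. Writes
#' `scores.csv`, `anova.json` and (optionally) summary figures; every
#' parameter and derived seed is echoed so a results directory is
#' self-describing.
#'
#' @param input_dir Directory produced by [simulate_trials()] (or with the
#'   same layout).
#' @param out_dir Results directory (created if missing).
#' @param config A [synergy_config()].
#' @param figures Write PNG summary figures (default TRUE).
#' @return Invisibly, the scores data frame.
#' @export
run_comparison <- function(input_dir, out_dir, config = synergy_config(),
                           figures = TRUE) {
  stopifnot(inherits(config, "synergy_config"))
  manifest_path <- file.path(input_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop_invalid("no manifest found at %s", manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (NROW(manifest) == 0) stop_invalid("manifest at %s lists no trials",
                                        manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message(sprintf("preprocessing %d trial(s): band-pass %g-%g Hz, envelope %g Hz, %d points",
                  nrow(manifest), config$bandpass_low_hz,
                  config$bandpass_high_hz, config$envelope_cutoff_hz,
                  config$n_points))
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    tr <- read_emg_trial(file.path(input_dir, manifest$file[i]))
    preprocess_trial(tr, config$bandpass_low_hz, config$bandpass_high_hz,
                     config$envelope_cutoff_hz, config$n_points)
  })

  k <- config$k
  if (identical(k, "auto")) {
    first_idx <- match(unique(manifest$condition), manifest$condition)
    ks <- vapply(first_idx, function(i)
      as.integer(select_synergy_count(trials[[i]], config$methods,
                                      config$k_range, config$vaf_threshold,
                                      seed = config$seed)), integer(1))
    k <- max(ks)
    message(sprintf("selected K = %d (VAF > %g%% for all methods)", k,
                    100 * config$vaf_threshold))
  }

  scores <- score_trials(trials, config$methods, k = k, seed = config$seed,
                         trial_info = manifest[, c("condition", "subject",
                                                   "trial")],
                         alpha = config$alpha)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)

  anova_out <- list()
  if (length(unique(manifest$subject)) >= 2 && length(config$methods) >= 2) {
    for (cond in unique(scores$condition)) {
      sub <- scores[scores$condition == cond, ]
      for (metric in c("vaf", "agreement_pct", "d_max")) {
        cmp <- compare_methods(sub, metric)
        anova_out[[cond]][[metric]] <-
          list(anova = cmp$anova, means = as.list(cmp$means),
               pairwise = cmp$pairwise)
      }
    }
  }
  jsonlite::write_json(
    list(k = k, config = unclass(config), comparisons = anova_out),
    file.path(out_dir, "anova.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", null = "null")

  if (figures) {
    for (metric in c("vaf", "agreement_pct", "d_max")) {
      grDevices::png(file.path(out_dir, sprintf("scores_%s.png", metric)),
                     width = 900, height = 500)
      plot_scores(scores, metric)
      grDevices::dev.off()
    }
  }
  message(sprintf("results written to %s (K = %d, seed %d)", out_dir, k,
                  config$seed))
  invisible(scores)
}

#' Bar summary of method scores
#'
#' Mean with standard-deviation error bars of a score metric, grouped by
#' factorisation method within condition.
#'
#' @param scores Data frame from [score_trials()] with a `condition` column.
#' @param metric Score column to plot.
#' @return Invisibly, the matrix of means.
#' @export
plot_scores <- function(scores, metric = c("vaf", "agreement_pct", "d_max")) {
  metric <- match.arg(metric)
  if (is.null(scores$condition)) scores$condition <- "all"
  mu <- tapply(scores[[metric]], list(scores$method, scores$condition), mean)
  sd_ <- tapply(scores[[metric]], list(scores$method, scores$condition),
                stats::sd)
  sd_[is.na(sd_)] <- 0
  ord <- intersect(c("walk", "slow_run", "moderate_run", "fast_run"),
                   colnames(mu))
  if (length(ord)) { mu <- mu[, ord, drop = FALSE]; sd_ <- sd_[, ord, drop = FALSE] }
  bp <- graphics::barplot(mu, beside = TRUE, legend.text = rownames(mu),
                          ylab = metric,
                          ylim = c(0, max(mu + sd_, na.rm = TRUE) * 1.15),
                          args.legend = list(x = "topright", bty = "n"))
  pos <- which(sd_ > 0)
  if (length(pos))
    graphics::arrows(bp[pos], mu[pos], bp[pos], (mu + sd_)[pos],
                     angle = 90, length = 0.03)
  invisible(mu)
}
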