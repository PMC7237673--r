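# Plain-text serialisation: trials as CSV + JSON sidecar, decompositions as
# W/H CSV + metadata, scores as CSV.

#' Read and write raw EMG trials
#'
#' A trial is stored as `<prefix>.csv` (one row per channel, first column
#' the channel label, remaining columns the samples) plus a JSON sidecar
#' `<prefix>.json` holding the sampling rate, gait-event sample indices,
#' condition label and seed.
#'
#' @param trial An `emg_trial` object.
#' @param prefix File path without extension.
#' @return `write_emg_trial()` returns the prefix invisibly;
#'   `read_emg_trial()` returns an `emg_trial`.
#' @export
write_emg_trial <- function(trial, prefix) {
  stopifnot(inherits(trial, "emg_trial"))
  df <- data.frame(channel = trial$channel_labels, trial$signal,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- sprintf("s%d", seq_len(ncol(trial$signal)))
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(fs_hz = trial$fs, events = trial$events,
               condition = trial$condition, seed = trial$seed,
               channel_labels = trial$channel_labels)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_emg_trial
#' @export
read_emg_trial <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  sig <- as.matrix(df[, -1, drop = FALSE])
  dimnames(sig) <- list(df$channel, NULL)
  structure(list(signal = sig, fs = meta$fs_hz,
                 events = as.integer(meta$events),
                 channel_labels = as.character(df$channel),
                 condition = meta$condition,
                 seed = as.integer(meta$seed %||% NA)),
            class = "emg_trial")
}

#' Read and write activation matrices
#'
#' @param x Activation matrix (muscles x time).
#' @param path CSV file path.
#' @return `read_activation()` returns the matrix with channel row names.
#' @export
write_activation <- function(x, path) {
  check_matrix(x)
  labels <- rownames(x) %||% sprintf("ch%02d", seq_len(nrow(x)))
  df <- data.frame(channel = labels, x, check.names = FALSE)
  names(df)[-1] <- sprintf("t%d", seq_len(ncol(x)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activation
#' @export
read_activation <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  dimnames(x) <- list(df$channel, NULL)
  x
}

#' Serialise a synergy decomposition to a directory
#'
#' Writes `W.csv` (muscle weights), `H.csv` (excitation primitives) and
#' `meta.json` (method, K, VAF, offset, mixing matrix, iteration info).
#'
#' @param fit A fitted `synergy` object.
#' @param dir Output directory (created if missing).
#' @return `read_synergy_fit()` returns a list with `w`, `h`, `offset`,
#'   `mixing` and metadata (not a refitted object).
#' @export
write_synergy_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "synergy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$w, file.path(dir, "W.csv"), row.names = FALSE)
  utils::write.csv(fit$h, file.path(dir, "H.csv"), row.names = FALSE)
  meta <- list(method = fit$method, k = fit$k, vaf = fit$vaf,
               offset = fit$offset, mixing = fit$mixing,
               iterations = fit$iterations,
               final_objective = if (!is.null(fit$objective))
                 utils::tail(fit$objective, 1) else NULL,
               channel_labels = fit$channel_labels)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_synergy_fit
#' @export
read_synergy_fit <- function(dir) {
  w <- as.matrix(utils::read.csv(file.path(dir, "W.csv")))
  h <- as.matrix(utils::read.csv(file.path(dir, "H.csv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dimnames(w) <- dimnames(h) <- NULL
  c(list(w = w, h = h), meta)
}
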