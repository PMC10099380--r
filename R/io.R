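# Reading, writing and epoching of recordings, label tracks, feature tables
# and evaluation reports. All formats are plain delimited text (plus JSON for
# reports) so fixtures and pipeline outputs stay diffable.

STATES <- c("normal", "hypnosis")

new_recording <- function(subject_id, fs, ecg, emg, t = NULL) {
  if (length(ecg) != length(emg)) stop("ecg and emg must have the same length")
  if (is.null(t)) t <- (seq_along(ecg) - 1) / fs
  if (length(t) != length(ecg)) stop("t, ecg, emg must have the same length")
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 t = as.numeric(t), ecg = as.numeric(ecg), emg = as.numeric(emg)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d samples at %g Hz (%.1f s)\n",
              x$subject_id, length(x$ecg), x$fs, length(x$ecg) / x$fs))
  invisible(x)
}

validate_recording <- function(rec, tol = 1e-6) {
  dt <- diff(rec$t)
  if (length(dt) > 0) {
    if (any(dt <= 0)) stop("recording time axis must be strictly increasing", call. = FALSE)
    if (max(abs(dt - 1 / rec$fs)) > tol) {
      stop(sprintf("non-uniform sampling: time steps deviate from 1/fs = %g s by more than %g s",
                   1 / rec$fs, tol), call. = FALSE)
    }
  }
  invisible(rec)
}

#' Write / read a recording as annotated CSV
#'
#' The format is a `# subject_id=<id> fs=<Hz>` comment line followed by a CSV
#' with header `t_s,ecg_mV,emg_mV`.
#'
#' @param rec a `recording` object.
#' @param path file path.
#' @return `read_recording` returns a `recording`; `write_recording` returns
#'   `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s fs=%.10g", rec$subject_id, rec$fs), con)
  writeLines("t_s,ecg_mV,emg_mV", con)
  writeLines(sprintf("%.10g,%.10g,%.10g", rec$t, rec$ecg, rec$emg), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*subject_id=(\\S+)\\s+fs=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 3L) {
    stop("recording file must start with a '# subject_id=<id> fs=<Hz>' line", call. = FALSE)
  }
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  needed <- c("t_s", "ecg_mV", "emg_mV")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop(sprintf("recording file is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  fs <- as.numeric(m[3])
  if (nrow(df) >= 3L) {
    med_dt <- stats::median(diff(df$t_s))
    if (abs(med_dt - 1 / fs) > 1e-6) {
      stop(sprintf("declared fs=%g Hz disagrees with the median time step %g s", fs, med_dt),
           call. = FALSE)
    }
  }
  validate_recording(new_recording(m[2], fs, df$ecg_mV, df$emg_mV, t = df$t_s))
}

validate_labels <- function(labels) {
  needed <- c("subject_id", "start_s", "end_s", "state")
  missing <- setdiff(needed, names(labels))
  if (length(missing) > 0) {
    stop(sprintf("label track is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!labels$state %in% STATES)) {
    stop(sprintf("label states must be one of: %s", paste(STATES, collapse = ", ")), call. = FALSE)
  }
  if (any(labels$start_s >= labels$end_s)) stop("label intervals must have start < end", call. = FALSE)
  for (id in unique(labels$subject_id)) {
    iv <- labels[labels$subject_id == id, , drop = FALSE]
    iv <- iv[order(iv$start_s), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start_s[-1] < iv$end_s[-nrow(iv)])) {
      stop(sprintf("label intervals overlap for subject %s", id), call. = FALSE)
    }
  }
  invisible(labels)
}

#' Write / read a label track CSV
#'
#' Plain CSV with header `subject_id,start_s,end_s,state`; intervals are
#' half-open `[start, end)` in seconds from recording start.
#'
#' @param labels data.frame of labeled intervals.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  validate_labels(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read an epoch feature table CSV
#'
#' Header `subject_id,state,epoch_start_s,ecg_S1,ecg_S2,ecg_S3,emg_S1,emg_S2,emg_S3`.
#'
#' @param features feature data.frame as produced by [extract_features()].
#' @param path file path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "state", "epoch_start_s", feature_columns())
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop(sprintf("feature table is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

feature_columns <- function() {
  c("ecg_S1", "ecg_S2", "ecg_S3", "emg_S1", "emg_S2", "emg_S3")
}

#' Write / read an evaluation report (JSON)
#'
#' @param report a list (typically from [run_pipeline()] or built from
#'   [cv_result_summary()] entries).
#' @param path file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

new_epoch <- function(subject_id, state, fs, ecg, emg, start_s) {
  structure(list(subject_id = subject_id, state = state, fs = fs,
                 ecg = ecg, emg = emg, start_s = start_s),
            class = "epoch")
}

#' Cut a labeled recording into fixed-length epochs
#'
#' Epochs are carved back to back, left to right, inside each labeled
#' interval; a trailing remainder shorter than `epoch_len` is discarded, and
#' no epoch ever spans an interval boundary, so each epoch inherits a single
#' unambiguous state.
#'
#' @param rec a `recording`.
#' @param labels label data.frame (same subject as `rec`).
#' @param epoch_len epoch length in seconds (> 0); default 5.
#' @return list of `epoch` objects, each with exactly `round(epoch_len * fs)`
#'   samples per channel.
#' @export
epoch_recording <- function(rec, labels, epoch_len = 5) {
  stopifnot_scalar_number(epoch_len, "epoch_len", 0, TRUE)
  validate_labels(labels)
  if (!all(labels$subject_id == rec$subject_id)) {
    stop(sprintf("label track subject(s) %s do not match recording subject %s",
                 paste(unique(labels$subject_id), collapse = ","), rec$subject_id),
         call. = FALSE)
  }
  n_samp <- round(epoch_len * rec$fs)
  total <- length(rec$ecg)
  epochs <- list()
  for (r in seq_len(nrow(labels))) {
    iv <- labels[r, ]
    n_ep <- floor((iv$end_s - iv$start_s) / epoch_len)
    if (n_ep < 1) next
    for (k in seq_len(n_ep)) {
      start_s <- iv$start_s + (k - 1) * epoch_len
      i0 <- round(start_s * rec$fs) + 1L
      i1 <- i0 + n_samp - 1L
      if (i1 > total) next  # interval extends past the recorded samples
      epochs[[length(epochs) + 1L]] <- new_epoch(
        rec$subject_id, iv$state, rec$fs,
        rec$ecg[i0:i1], rec$emg[i0:i1], start_s)
    }
  }
  epochs
}
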