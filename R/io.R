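#' @name io
#' @title Recording and report I/O
NULL

#' Write a recording as a two-column CSV
#'
#' Columns `time_s` and `amplitude`; sampling rate, subject id and
#' condition travel in a commented header line so a round trip restores the
#' full object.
#'
#' @param recording a `vf_recording`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g subject_id=%s condition=%s", recording$fs,
                     recording$subject_id, recording$condition), con)
  writeLines("time_s,amplitude", con)
  t <- (seq_along(recording$samples) - 1) / recording$fs
  writeLines(paste(format(t, trim = TRUE), recording$samples, sep = ","), con)
  invisible(path)
}

#' Load a recording from a two-column CSV
#'
#' Expects the layout written by [write_recording()]: an optional commented
#' metadata line, a `time_s,amplitude` header, then strictly increasing
#' time stamps.
#'
#' @param path CSV path.
#' @return a `vf_recording`.
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) vf_input_error("no such file: %s", path)
  first <- readLines(path, n = 1)
  meta <- list(fs = NA_real_, subject_id = "unknown", condition = "control")
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    for (kv in strsplit(sub("^#\\s*", "", first), "\\s+")[[1]]) {
      p <- strsplit(kv, "=")[[1]]
      if (length(p) == 2) meta[[p[1]]] <- p[2]
    }
  }
  df <- utils::read.csv(path, skip = skip)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    vf_input_error("expected columns time_s, amplitude in %s", path)
  if (any(diff(df$time_s) <= 0))
    vf_input_error("non-monotone time column in %s", path)
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (!is.finite(fs)) fs <- round(1 / stats::median(diff(df$time_s)))
  new_vf_recording(df$amplitude, fs, meta$subject_id, meta$condition,
                   length(df$amplitude) / fs)
}

#' Write an accuracy report as CSV
#'
#' One row in the conventional table layout: per-class accuracies in the
#' order ANSB, flecainide, amiodarone, diltiazem, control, then overall.
#'
#' @param report a `vf_report` (or named list of them; one row each).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  reports <- if (inherits(report, "vf_report")) list(report = report) else report
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    vals <- stats::setNames(rep(NA_real_, length(CLASS_ORDER)), CLASS_ORDER)
    vals[names(r$per_class_accuracy)] <- r$per_class_accuracy
    data.frame(experiment = nm, t(vals), overall = r$overall_accuracy,
               n_windows = r$n_test_windows, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
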