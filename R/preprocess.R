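#' @name preprocess
#' @title Signal restoration, decimation, windowing, and subject splits
NULL

# Rolling standard deviation over a centered window of `w` samples,
# computed from cumulative sums (O(n)).
rolling_sd <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  half <- w %/% 2
  lo <- pmax(0, seq_len(n) - half - 1)         # index into cs (0-based window lo)
  hi <- pmin(n, seq_len(n) + (w - half - 1))
  cnt <- hi - lo
  m <- (cs[hi + 1] - cs[lo + 1]) / cnt
  v <- (cs2[hi + 1] - cs2[lo + 1]) / cnt - m^2
  sqrt(pmax(v, 0))
}

# Runs of >= min_len consecutive exactly-identical samples whose absolute
# value is at least sat_frac of the recording peak: the signature of a
# saturated (clipped) segment.
find_saturated_runs <- function(x, min_len = 3, sat_frac = 0.4) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$lengths >= min_len & abs(r$values) >= sat_frac * max(abs(x))
  data.frame(start = starts[keep], end = ends[keep])
}

#' Restore clipped or transient-corrupted samples
#'
#' Two kinds of samples are flagged: (i) samples inside 5-ms windows whose
#' local standard deviation exceeds `std_threshold` times the recording's
#' median local standard deviation (sharp transients, e.g. rail edges), and
#' (ii) saturated runs of at least three identical high-amplitude samples.
#' Flagged std-transient samples are replaced by a running median of length
#' `median_len_ms`; flagged saturated runs are bridged by linear
#' interpolation through the surrounding unflagged samples, which removes
#' the flat rail segments that hard clipping leaves behind. All unflagged
#' samples pass through bit-identically.
#'
#' @param recording a `vf_recording`.
#' @param local_window_ms width of the local-standard-deviation window
#'   (milliseconds, default 5).
#' @param std_threshold flag multiplier over the median local standard
#'   deviation (default 4).
#' @param median_len_ms running-median length for transient replacement
#'   (milliseconds; forced odd in samples).
#' @return a restored `vf_recording`.
#' @export
restore_clipping <- function(recording, local_window_ms = 5,
                             std_threshold = 4, median_len_ms = 25) {
  if (!inherits(recording, "vf_recording")) vf_input_error("recording must be a vf_recording")
  x <- recording$samples
  n <- length(x)
  w <- max(2, round(local_window_ms * recording$fs / 1000))
  if (n < w) vf_input_error("recording shorter than one local window")
  if (max(abs(x)) == 0 || stats::sd(x) == 0) return(recording)  # constant signal
  sds <- rolling_sd(x, w)
  med_sd <- stats::median(sds)
  hi_var <- if (med_sd > 0) sds > std_threshold * med_sd else rep(FALSE, n)
  sat <- find_saturated_runs(x)
  sat_mask <- rep(FALSE, n)
  for (k in seq_len(nrow(sat))) sat_mask[sat$start[k]:sat$end[k]] <- TRUE
  if (mean(sat_mask) > 0.6) sat_mask[] <- FALSE  # degenerate: mostly-flat signal
  y <- x
  if (any(hi_var & !sat_mask)) {
    mlen <- round(median_len_ms * recording$fs / 1000)
    if (mlen %% 2 == 0) mlen <- mlen + 1
    med <- stats::runmed(x, mlen, endrule = "median")
    idx <- which(hi_var & !sat_mask)
    y[idx] <- med[idx]
  }
  if (any(sat_mask)) {
    good <- which(!sat_mask)
    bad <- which(sat_mask)
    y[bad] <- stats::approx(good, y[good], xout = bad, rule = 2)$y
  }
  out <- new_vf_recording(y, recording$fs, recording$subject_id,
                          recording$condition, recording$duration_s)
  out
}

#' Decimate a recording by a factor of ten
#'
#' Anti-alias filtering uses a Chebyshev Type I IIR low-pass of order 8
#' (0.05 dB passband ripple, cutoff at 0.8 of the output Nyquist) applied
#' forward-backward (zero phase), then every tenth sample is kept. The
#' filter numerator is rescaled so the DC gain is exactly one, removing the
#' even-order Chebyshev ripple offset at 0 Hz.
#'
#' @param recording a `vf_recording` whose `fs` is divisible by 10.
#' @return a `vf_recording` at `fs/10` with `floor(n/10)` samples.
#' @export
decimate_by_ten <- function(recording) {
  if (!inherits(recording, "vf_recording")) vf_input_error("recording must be a vf_recording")
  if (recording$fs %% 10 != 0) vf_input_error("fs must be divisible by 10")
  x <- recording$samples
  wc <- 0.8 / 10                     # normalized cutoff (fraction of input Nyquist)
  flt <- signal::cheby1(8, 0.05, wc, type = "low")
  dc_gain <- sum(flt$b) / sum(flt$a)
  flt$b <- flt$b / dc_gain           # exact unity DC response
  y <- signal::filtfilt(flt, x)
  keep <- seq(1, 10 * floor(length(x) / 10), by = 10)
  new_vf_recording(y[keep], recording$fs / 10, recording$subject_id,
                   recording$condition, recording$duration_s)
}

#' Scale data by the training-set peak
#'
#' Divides by `max(abs(train_reference))`; the same scalar is reused for
#' test data so no test-set information leaks into the preprocessing.
#'
#' @param x numeric vector or matrix to scale.
#' @param train_reference numeric vector or matrix of training-set values.
#' @return `x / max(abs(train_reference))`, with the scalar attached as the
#'   `"scale"` attribute.
#' @export
normalize_to_train_max <- function(x, train_reference) {
  if (length(train_reference) == 0) vf_input_error("empty training reference")
  s <- max(abs(train_reference))
  if (s == 0) vf_degenerate_error("all-zero training reference")
  out <- x / s
  attr(out, "scale") <- s
  out
}

#' Cut a recording into fixed-length rectangular windows
#'
#' Window starts are `0, hop, 2*hop, ...`; trailing samples that do not fill
#' a complete window are dropped, so the count is
#' `floor((n - window_length)/hop) + 1`.
#'
#' @param recording a `vf_recording`.
#' @param window_length window length in samples.
#' @param hop hop (window_length minus overlap) in samples.
#' @return a `vf_windowset`: list with `windows`
#'   (n_windows x window_length matrix), `window_length`, `hop`, `fs`,
#'   `subject_ids`, `labels`, `t_start` (seconds).
#' @export
window_signal <- function(recording, window_length, hop) {
  if (!inherits(recording, "vf_recording")) vf_input_error("recording must be a vf_recording")
  n <- length(recording$samples)
  if (hop <= 0 || window_length < hop) vf_input_error("need 0 < hop <= window_length")
  if (window_length > n) vf_input_error("signal shorter than window_length")
  n_win <- floor((n - window_length) / hop) + 1
  starts <- (seq_len(n_win) - 1) * hop
  idx <- outer(starts, seq_len(window_length), `+`)
  W <- matrix(recording$samples[idx], nrow = n_win)
  structure(list(windows = W, window_length = window_length, hop = hop,
                 fs = recording$fs,
                 subject_ids = rep(recording$subject_id, n_win),
                 labels = rep(recording$condition, n_win),
                 t_start = starts / recording$fs),
            class = "vf_windowset")
}

#' Stack the windowsets of several recordings into one
#'
#' @param windowsets list of `vf_windowset` objects with identical
#'   window_length/hop/fs.
#' @return a single combined `vf_windowset`.
#' @export
bind_windowsets <- function(windowsets) {
  stopifnot(length(windowsets) > 0)
  wl <- unique(vapply(windowsets, `[[`, 0, "window_length"))
  hp <- unique(vapply(windowsets, `[[`, 0, "hop"))
  fs <- unique(vapply(windowsets, `[[`, 0, "fs"))
  if (length(wl) != 1 || length(hp) != 1 || length(fs) != 1)
    vf_input_error("windowsets have inconsistent geometry")
  structure(list(windows = do.call(rbind, lapply(windowsets, `[[`, "windows")),
                 window_length = wl, hop = hp, fs = fs,
                 subject_ids = unlist(lapply(windowsets, `[[`, "subject_ids")),
                 labels = unlist(lapply(windowsets, `[[`, "labels")),
                 t_start = unlist(lapply(windowsets, `[[`, "t_start"))),
            class = "vf_windowset")
}

#' Build a subject-exclusive train/test split plan
#'
#' @param train_subjects,test_subjects character vectors of subject ids.
#' @return a `vf_splitplan` list.
#' @export
split_plan <- function(train_subjects, test_subjects) {
  if (length(intersect(train_subjects, test_subjects)) > 0)
    vf_input_error("subjects appear in both train and test sets")
  structure(list(train_subjects = unique(train_subjects),
                 test_subjects = unique(test_subjects)),
            class = "vf_splitplan")
}

#' Default 15/12 split for the standard 27-subject cohort
#'
#' The first three subjects of each condition train; the remainder test
#' (1 ANSB, 3 flecainide, 2 amiodarone, 3 diltiazem, 3 control with the
#' default cohort counts).
#'
#' @param cohort list of `vf_recording` objects.
#' @param n_train_per_condition training subjects per condition (default 3).
#' @return a `vf_splitplan`.
#' @export
default_split_plan <- function(cohort, n_train_per_condition = 3) {
  ids <- vapply(cohort, `[[`, "", "subject_id")
  conds <- vapply(cohort, `[[`, "", "condition")
  train <- unlist(lapply(split(ids, conds), function(s)
    head(sort(s), n_train_per_condition)))
  split_plan(train, setdiff(ids, train))
}

#' Partition a cohort by a split plan
#'
#' @param recordings list of `vf_recording` objects.
#' @param plan a `vf_splitplan`.
#' @return `list(train = ..., test = ...)` of recording lists.
#' @export
subject_split <- function(recordings, plan) {
  ids <- vapply(recordings, `[[`, "", "subject_id")
  planned <- c(plan$train_subjects, plan$test_subjects)
  missing <- setdiff(planned, ids)
  if (length(missing) > 0)
    vf_input_error("unknown subject id(s) in plan: %s", paste(missing, collapse = ", "))
  list(train = recordings[ids %in% plan$train_subjects],
       test = recordings[ids %in% plan$test_subjects])
}

#' Keep the second half of a recording
#'
#' Returns the last `ceiling(n/2)` samples; used to focus on the late
#' (ischemic) phase of the VF episode where drug effects are most visible.
#'
#' @param recording a `vf_recording`.
#' @return a `vf_recording` of the trailing half.
#' @export
take_second_half <- function(recording) {
  if (!inherits(recording, "vf_recording")) vf_input_error("recording must be a vf_recording")
  n <- length(recording$samples)
  if (n < 2) vf_input_error("recording too short to halve")
  keep <- (n - ceiling(n / 2) + 1):n
  new_vf_recording(recording$samples[keep], recording$fs, recording$subject_id,
                   recording$condition, length(keep) / recording$fs)
}
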