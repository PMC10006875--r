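#' @name audio_features
#' @title Psychoacoustic filterbanks and the eleven spectral descriptors
#'
#' @description
#' Audio content analysis summarizes a short-time spectrum with a handful of
#' shape descriptors, usually after pooling FFT bins into perceptually
#' motivated bands (Mel, Bark, ERB). VF lives below ~30 Hz, so the bands are
#' warped onto a 0-50 Hz cap instead of the audible range. Eleven
#' descriptors are computed per analysis window: spectral centroid, spread,
#' skewness, kurtosis, entropy, flatness, crest, flux, slope, decrease, and
#' rolloff.
NULL

AUDIO_FEATURE_NAMES <- c("centroid", "spread", "skewness", "kurtosis",
                         "entropy", "flatness", "crest", "flux", "slope",
                         "decrease", "rolloff")

#' Convert frequency to psychoacoustic scale units
#'
#' Mel: `2595 log10(1 + f/700)`; Bark: `13 atan(0.00076 f) +
#' 3.5 atan((f/7500)^2)`; ERB-rate: `21.4 log10(1 + 0.00437 f)`;
#' linear: identity. All are strictly increasing in `f`.
#'
#' @param f frequency (Hz), non-negative; vectorized.
#' @param scale one of `"linear"`, `"mel"`, `"bark"`, `"erb"`.
#' @return scale units.
#' @export
scale_convert <- function(f, scale) {
  if (any(f < 0)) vf_input_error("negative frequency")
  switch(match.arg(scale, c("linear", "mel", "bark", "erb")),
         linear = f,
         mel = 2595 * log10(1 + f / 700),
         bark = 13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2),
         erb = 21.4 * log10(1 + 0.00437 * f))
}

# Inverse of scale_convert by monotone root finding (no closed form needed
# at the precision used for band-edge placement).
scale_invert <- function(u, scale, f_max) {
  if (scale == "linear") return(u)
  vapply(u, function(ui) {
    if (ui <= 0) return(0)
    stats::uniroot(function(f) scale_convert(f, scale) - ui,
                   lower = 0, upper = f_max * 1.001, tol = 1e-10)$root
  }, 0)
}

#' Build a triangular filterbank on a (possibly warped) frequency scale
#'
#' Band edges are equally spaced in scale units between
#' `scale_convert(f_low)` and `scale_convert(f_high)` and mapped back to Hz;
#' band `b` is the triangle spanning edges `b` to `b+2`, peaking at `b+1`.
#' Rows are normalized to sum to one. A band so narrow that it covers no
#' FFT bin (possible with many warped bands on a coarse FFT grid) receives
#' unit weight on the bin nearest its centre, so every band always carries
#' energy and normalization is well defined.
#'
#' @param scale `"linear"`, `"mel"`, `"bark"`, or `"erb"`.
#' @param n_bands number of bands (>= 1).
#' @param f_low,f_high band limits in Hz (defaults 0 and 50).
#' @param fft_freqs vector of FFT bin frequencies (Hz).
#' @return a `vf_filterbank`: list with `scale`, `n_bands`, `f_low`,
#'   `f_high`, `weights` (n_bands x length(fft_freqs)), `centers` (Hz).
#' @export
build_filterbank <- function(scale, n_bands, f_low = 0, f_high = 50, fft_freqs) {
  scale <- match.arg(scale, c("linear", "mel", "bark", "erb"))
  if (n_bands < 1) vf_input_error("n_bands must be >= 1")
  if (f_low >= f_high) vf_input_error("need f_low < f_high")
  if (f_high > max(fft_freqs) + 1e-9)
    vf_config_error("f_high beyond the available FFT grid")
  u <- seq(scale_convert(f_low, scale), scale_convert(f_high, scale),
           length.out = n_bands + 2)
  edges <- scale_invert(u, scale, f_high)
  W <- matrix(0, n_bands, length(fft_freqs))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; cen <- edges[b + 1]; hi <- edges[b + 2]
    up <- (fft_freqs - lo) / max(cen - lo, 1e-12)
    dn <- (hi - fft_freqs) / max(hi - cen, 1e-12)
    W[b, ] <- pmax(0, pmin(up, dn))
    if (sum(W[b, ]) == 0) W[b, which.min(abs(fft_freqs - cen))] <- 1
  }
  W <- W / rowSums(W)
  structure(list(scale = scale, n_bands = n_bands, f_low = f_low,
                 f_high = f_high, weights = W, centers = edges[2:(n_bands + 1)]),
            class = "vf_filterbank")
}

#' Apply a filterbank to a spectrum
#'
#' @param x non-negative spectrum (magnitude or power) on the filterbank's
#'   FFT grid.
#' @param fb a `vf_filterbank`.
#' @return vector of `n_bands` band values.
#' @export
band_energies <- function(x, fb) {
  if (length(x) != ncol(fb$weights))
    vf_input_error("spectrum length %d does not match filterbank grid %d",
                   length(x), ncol(fb$weights))
  as.numeric(fb$weights %*% x)
}

#' The eleven spectral shape descriptors of one frame
#'
#' With band values `s_k` at centre frequencies `f_k` and
#' `p_k = s_k / sum(s)`:
#' centroid `mu = sum f_k p_k`; spread `sqrt(sum (f_k - mu)^2 p_k)`;
#' skewness and kurtosis are the third and fourth standardized moments
#' (both 0 by convention for a zero-spread point mass); entropy
#' `-sum p log p / log N` (normalized to `[0,1]`); flatness
#' `geomean(s)/mean(s)`; crest `max(s)/mean(s)`; flux is the Euclidean
#' distance to the previous frame's band values (0 for the first frame);
#' slope is the least-squares slope of `s` on `f`; decrease is
#' `sum_{k>=2} (s_k - s_1)/(k - 1) / sum_{k>=2} s_k`; rolloff is the
#' smallest `f_r` whose cumulative energy reaches 95%.
#'
#' @param s non-negative band values, not all zero.
#' @param f band centre frequencies (Hz).
#' @param s_prev previous frame's band values, or `NULL` for the first
#'   frame.
#' @return named numeric vector of length 11 (order: centroid, spread,
#'   skewness, kurtosis, entropy, flatness, crest, flux, slope, decrease,
#'   rolloff).
#' @export
descriptor_vector <- function(s, f, s_prev = NULL) {
  if (length(s) != length(f)) vf_input_error("band values and centers differ in length")
  if (any(s < 0)) vf_input_error("negative band values")
  tot <- sum(s)
  if (tot == 0) vf_degenerate_error("all-zero frame")
  p <- s / tot
  mu <- sum(f * p)
  spread <- sqrt(sum((f - mu)^2 * p))
  if (spread > 1e-12) {
    skew <- sum((f - mu)^3 * p) / spread^3
    kurt <- sum((f - mu)^4 * p) / spread^4
  } else {
    skew <- 0; kurt <- 0
  }
  pos <- p[p > 0]
  entropy <- if (length(p) > 1) -sum(pos * log(pos)) / log(length(p)) else 0
  flatness <- if (any(s == 0)) 0 else exp(mean(log(s))) / mean(s)
  crest <- max(s) / mean(s)
  flux <- if (is.null(s_prev)) 0 else sqrt(sum((s - s_prev)^2))
  fc <- f - mean(f)
  slope <- sum(fc * (s - mean(s))) / sum(fc^2)
  n <- length(s)
  decrease <- if (n > 1 && sum(s[-1]) > 0)
    sum((s[-1] - s[1]) / (seq_len(n - 1))) / sum(s[-1]) else 0
  rolloff <- f[which(cumsum(p) >= 0.95 - 1e-12)[1]]
  c(centroid = mu, spread = spread, skewness = skew, kurtosis = kurt,
    entropy = entropy, flatness = flatness, crest = crest, flux = flux,
    slope = slope, decrease = decrease, rolloff = rolloff)
}

#' Eleven-descriptor feature matrix for a windowset
#'
#' Per window: magnitude spectrum (zero-padded FFT), band pooling, then
#' [descriptor_vector()]. With `scale = "none"` the raw FFT bins at or below
#' `f_high` are used directly as bands (the low-pass VF band needs no
#' auditory warping); otherwise a [build_filterbank()] pooling is applied.
#' Flux chains consecutive windows within each recording only, restarting
#' at 0 whenever the subject id changes.
#'
#' @param windowset a `vf_windowset`.
#' @param scale `"none"`, `"linear"`, `"mel"`, `"bark"`, or `"erb"`.
#' @param n_bands number of bands (ignored for `"none"`).
#' @param f_high band cap in Hz (default 50).
#' @param nfft FFT length (default 4096).
#' @return matrix n_windows x 11 with descriptor column names and
#'   `subject_ids`/`labels` attributes.
#' @export
audio_feature_matrix <- function(windowset, scale = "none", n_bands = 64,
                                 f_high = 50, nfft = 4096) {
  fft_freqs <- (seq_len(nfft %/% 2 + 1) - 1) * windowset$fs / nfft
  if (scale == "none") {
    keep <- which(fft_freqs <= f_high + 1e-9)
    centers <- fft_freqs[keep]
  } else {
    fb <- build_filterbank(scale, n_bands, 0, f_high, fft_freqs)
    centers <- fb$centers
  }
  n <- nrow(windowset$windows)
  # batch the FFTs (mvfft on columns) and the band pooling (one product)
  Z <- rbind(t(windowset$windows),
             matrix(0, nfft - windowset$window_length, n))
  M <- abs(stats::mvfft(Z))[seq_len(nfft %/% 2 + 1), , drop = FALSE]
  S <- if (scale == "none") M[keep, , drop = FALSE] else fb$weights %*% M
  out <- matrix(NA_real_, n, 11, dimnames = list(NULL, AUDIO_FEATURE_NAMES))
  prev <- NULL; prev_subject <- ""
  for (i in seq_len(n)) {
    s <- S[, i]
    if (windowset$subject_ids[i] != prev_subject) prev <- NULL
    out[i, ] <- descriptor_vector(s, centers, prev)
    prev <- s; prev_subject <- windowset$subject_ids[i]
  }
  attr(out, "subject_ids") <- windowset$subject_ids
  attr(out, "labels") <- windowset$labels
  out
}

#' Z-score features with training-set statistics
#'
#' @param x numeric matrix (windows x features).
#' @param stats `NULL` to fit mean/sd on `x` itself (training), or the
#'   `"stats"` attribute of a previously normalized training matrix (test).
#' @return normalized matrix with the fitted `"stats"` attached as an
#'   attribute.
#' @export
zscore_normalize <- function(x, stats = NULL) {
  if (is.null(stats)) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    if (any(sd == 0)) vf_degenerate_error("zero-variance feature column")
    stats <- list(mean = mu, sd = sd)
  }
  out <- sweep(sweep(x, 2, stats$mean), 2, stats$sd, `/`)
  attr(out, "stats") <- stats
  attr(out, "subject_ids") <- attr(x, "subject_ids")
  attr(out, "labels") <- attr(x, "labels")
  out
}

#' Whole-sequence feature tracks of one recording
#'
#' Computes the eleven descriptors on short sliding windows over the entire
#' recording (1000-sample windows, 200-sample hop by default), producing
#' one track of 1796 values per feature on a standard 360,000-sample
#' recording. Concatenating all eleven tracks feature-major yields the
#' 19,756-dimensional whole-sequence input vector.
#'
#' @param recording a `vf_recording`.
#' @param scale,n_bands filterbank configuration (default ERB, 256 bands).
#' @param window_length,hop track windowing (defaults 1000/200).
#' @param f_high,nfft spectral configuration.
#' @return a `vf_feature_tracks`: list with `tracks` (11 x n_track_windows),
#'   `feature_names`, `window_length`, `hop`, `subject_id`, `label`.
#' @export
whole_sequence_tracks <- function(recording, scale = "erb", n_bands = 256,
                                  window_length = 1000, hop = 200,
                                  f_high = 50, nfft = 4096) {
  ws <- window_signal(recording, window_length, hop)
  fm <- audio_feature_matrix(ws, scale = scale, n_bands = n_bands,
                             f_high = f_high, nfft = nfft)
  structure(list(tracks = t(unclass(fm)[, , drop = FALSE]),
                 feature_names = AUDIO_FEATURE_NAMES,
                 window_length = window_length, hop = hop,
                 subject_id = recording$subject_id, label = recording$condition),
            class = "vf_feature_tracks")
}

#' Concatenate selected feature tracks into one input vector
#'
#' @param tracks a `vf_feature_tracks`.
#' @param features indices or names of the features to keep (default all).
#' @return numeric vector, feature-major (track 1 fully, then track 2, ...).
#' @export
concat_tracks <- function(tracks, features = seq_len(nrow(tracks$tracks))) {
  if (is.character(features)) features <- match(features, tracks$feature_names)
  as.numeric(t(tracks$tracks[features, , drop = FALSE]))
}
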