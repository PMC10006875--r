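#' @name spectral
#' @title Short-time spectral estimation for VF windows
#'
#' @description
#' VF carries essentially all of its discriminative power below 20 Hz, so
#' the spectral feature space is the squared-magnitude short-time Fourier
#' transform with rectangular windows (2048 samples, 50% overlap at
#' 1 kHz by default) and, per analysis window, a Welch periodogram
#' (512-sample rectangular segments, 256-sample overlap) restricted to the
#' 0-16 Hz band. All estimates are one-sided power spectral densities
#' (power per Hz), so integrating over frequency recovers the signal power.
NULL

# One-sided PSD of one zero-padded segment; rectangular window.
# Density scaling: integral of the one-sided PSD over [0, fs/2] equals the
# mean square of the segment.
segment_psd <- function(x, fs, nfft) {
  nseg <- length(x)
  X <- stats::fft(c(x, numeric(nfft - nseg)))
  nb <- nfft %/% 2 + 1
  p <- abs(X[seq_len(nb)])^2 / (fs * nseg)
  mult <- rep(2, nb); mult[1] <- 1
  if (nfft %% 2 == 0) mult[nb] <- 1
  p * mult
}

#' Spectrogram (squared-magnitude STFT, rectangular window)
#'
#' @param recording a `vf_recording`.
#' @param window_length frame length in samples (default 2048).
#' @param overlap frame overlap in samples (default `window_length/2`).
#' @return a `vf_spectrogram`: list with `power`
#'   (n_frames x n_bins PSD matrix), `times` (frame centers, s), `freqs`
#'   (Hz), `window_length`, `hop`.
#' @export
stft_spectrogram <- function(recording, window_length = 2048,
                             overlap = window_length / 2) {
  if (overlap < 0 || overlap >= window_length)
    vf_input_error("need 0 <= overlap < window_length")
  hop <- window_length - overlap
  ws <- window_signal(recording, window_length, hop)
  P <- t(apply(ws$windows, 1, segment_psd, fs = recording$fs, nfft = window_length))
  nb <- window_length %/% 2 + 1
  structure(list(power = P,
                 times = ws$t_start + window_length / (2 * recording$fs),
                 freqs = (seq_len(nb) - 1) * recording$fs / window_length,
                 window_length = window_length, hop = hop),
            class = "vf_spectrogram")
}

#' Welch averaged periodogram of one analysis window
#'
#' @param window numeric vector of samples.
#' @param fs sampling rate (Hz).
#' @param segment Welch segment length in samples (default 512).
#' @param seg_overlap segment overlap in samples (default 256).
#' @param nfft FFT length; segments are zero-padded to `nfft`
#'   (default 4096, which at 1 kHz gives the 0.244 Hz grid that puts 67
#'   bins in the 0-16 Hz band).
#' @return a `vf_psd`: list with `psd` (one-sided density), `freqs` (Hz),
#'   `n_bins`.
#' @export
welch_psd <- function(window, fs, segment = 512, seg_overlap = 256, nfft = 4096) {
  if (segment > length(window)) vf_input_error("segment longer than window")
  if (seg_overlap < 0 || seg_overlap >= segment)
    vf_input_error("need 0 <= seg_overlap < segment")
  if (nfft < segment) vf_input_error("nfft must be >= segment")
  hop <- segment - seg_overlap
  n_seg <- floor((length(window) - segment) / hop) + 1
  starts <- (seq_len(n_seg) - 1) * hop
  acc <- 0
  for (s in starts) acc <- acc + segment_psd(window[(s + 1):(s + segment)], fs, nfft)
  nb <- nfft %/% 2 + 1
  structure(list(psd = acc / n_seg, freqs = (seq_len(nb) - 1) * fs / nfft,
                 n_bins = nb),
            class = "vf_psd")
}

#' Restrict a periodogram to the low VF band
#'
#' Keeps every bin strictly below `f_cap` plus the first bin at or above it,
#' so the band edge is always covered. With the defaults (nfft 4096 at
#' 1 kHz, cap 16 Hz) this yields exactly 67 values (0 to ~16.11 Hz),
#' matching the 67-neuron input/output layer of the spectral autoencoder.
#'
#' @param psd a `vf_psd`.
#' @param f_cap band cap in Hz (default 16).
#' @return numeric vector of PSD values with a `"freqs"` attribute.
#' @export
low_band_vector <- function(psd, f_cap = 16) {
  if (f_cap <= 0) vf_input_error("f_cap must be > 0")
  fs_nyq <- max(psd$freqs)
  if (f_cap > fs_nyq) vf_input_error("f_cap beyond Nyquist (%g Hz)", fs_nyq)
  k <- sum(psd$freqs < f_cap) + 1
  k <- min(k, length(psd$psd))
  out <- psd$psd[seq_len(k)]
  attr(out, "freqs") <- psd$freqs[seq_len(k)]
  out
}

#' Dominant frequency of a periodogram
#'
#' Frequency of the maximum PSD bin, excluding DC. For VF windows this is
#' the conventional dominant-frequency statistic, typically 5-10 Hz.
#'
#' @param psd a `vf_psd`.
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(psd) {
  p <- psd$psd
  if (all(p == 0)) vf_degenerate_error("all-zero periodogram")
  k <- which.max(p[-1]) + 1
  psd$freqs[k]
}

#' Spectral (0-16 Hz Welch periodogram) feature matrix for a windowset
#'
#' Per analysis window: Welch periodogram, then the low-band restriction.
#'
#' @param windowset a `vf_windowset` (2048/1024 windows by default use).
#' @param f_cap band cap in Hz.
#' @param segment,seg_overlap,nfft forwarded to [welch_psd()].
#' @return matrix n_windows x n_band_bins (67 under the defaults), with the
#'   windowset's `subject_ids`/`labels` attached as attributes.
#' @export
spectral_feature_matrix <- function(windowset, f_cap = 16, segment = 512,
                                    seg_overlap = 256, nfft = 4096) {
  rows <- lapply(seq_len(nrow(windowset$windows)), function(i) {
    p <- welch_psd(windowset$windows[i, ], windowset$fs, segment, seg_overlap, nfft)
    as.numeric(low_band_vector(p, f_cap))
  })
  out <- do.call(rbind, rows)
  attr(out, "subject_ids") <- windowset$subject_ids
  attr(out, "labels") <- windowset$labels
  out
}
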