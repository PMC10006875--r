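#' @name synthetic_vf
#' @title Synthetic ventricular-fibrillation signal generator
#'
#' @description
#' The experimental recordings this package was designed around (single-lead
#' surface ECG during induced VF in anesthetized dogs, five conditions:
#' control, amiodarone, diltiazem, flecainide, and autonomic nervous system
#' blockade) are not publicly deposited. The generator in this file emulates
#' their published spectro-temporal structure so that every downstream stage
#' is testable: narrowband activity with dominant frequency between 5 and
#' 10 Hz, a pronounced frequency drop roughly 50 s after VF onset, and a
#' condition-specific "rotated Y" bifurcation (fork) of the spectral ridge.
#' Signals are sums of one (pre-fork) or two (post-fork) frequency-modulated
#' oscillators riding on broadband noise; no cardiac electrophysiology is
#' modelled.
NULL

VF_CONDITIONS <- c("control", "amiodarone", "diltiazem", "flecainide", "ansb")

#' Build the per-condition spectro-temporal template
#'
#' Encodes the qualitative condition fingerprints as numeric parameters:
#' control has the most erratic (highest-variance) frequency trajectory and
#' no stable fork; diltiazem has the highest starting frequency and the
#' widest fork dispersion; amiodarone has a narrow frequency range and an
#' abrupt fork; flecainide has no fork, the narrowest bandwidth, and the
#' deepest late drop in frequency; ANSB forks with a per-subject random
#' onset delay drawn uniformly from 60-120 s.
#'
#' @param condition one of `"control"`, `"amiodarone"`, `"diltiazem"`,
#'   `"flecainide"`, `"ansb"`.
#' @param seed integer seed; only ANSB uses randomness (its fork onset).
#' @return an object of class `vf_template` with fields `condition`,
#'   `f0_start` (Hz), `f0_drop_time` (s), `drop_mag` (Hz), `fork_onset`
#'   (s, `NA` when the ridge never splits), `fork_ramp` (s),
#'   `fork_separation` (Hz), `bandwidth` (Hz), `drift_sd` (Hz),
#'   `noise_floor` (noise/signal power ratio), `amplitude`.
#' @export
make_condition_template <- function(condition, seed = 0L) {
  if (length(condition) != 1 || !condition %in% VF_CONDITIONS)
    vf_input_error("unknown condition label '%s'", paste(condition, collapse = ","))
  base <- list(
    condition = condition,
    f0_start = 7.0, f0_drop_time = 50, drop_mag = 1.2,
    fork_onset = NA_real_, fork_ramp = 12, fork_separation = 0,
    bandwidth = 1.0, drift_sd = 0.3, noise_floor = 0.05, amplitude = 1.0)
  tpl <- switch(condition,
    control = modifyList(base, list(
      bandwidth = 1.5, drift_sd = 0.35, drop_mag = 1.5)),
    amiodarone = modifyList(base, list(
      f0_start = 6.7, drop_mag = 1.0, fork_onset = 55, fork_ramp = 2,
      fork_separation = 2.0, bandwidth = 0.8, drift_sd = 0.2)),
    diltiazem = modifyList(base, list(
      f0_start = 7.3, drop_mag = 1.0, fork_onset = 60, fork_separation = 3.0,
      bandwidth = 1.2, drift_sd = 0.3)),
    flecainide = modifyList(base, list(
      drop_mag = 2.5, bandwidth = 0.4, drift_sd = 0.1)),
    ansb = modifyList(base, list(
      fork_onset = with_seed(derive_seed(seed, "ansb-fork"), runif(1, 60, 120)),
      fork_separation = 2.5, bandwidth = 1.0, drift_sd = 0.25)))
  structure(tpl, class = "vf_template")
}

#' @export
print.vf_template <- function(x, ...) {
  cat(sprintf("<vf_template %s> f0 %.1f Hz, drop %.1f Hz @ %.0f s, fork %s, bw %.2f Hz\n",
              x$condition, x$f0_start, x$drop_mag, x$f0_drop_time,
              if (is.na(x$fork_onset)) "none"
              else sprintf("%.0f s (sep %.1f Hz)", x$fork_onset, x$fork_separation),
              x$bandwidth))
  invisible(x)
}

new_vf_recording <- function(samples, fs, subject_id, condition, duration_s) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, condition = condition,
                 duration_s = duration_s),
            class = "vf_recording")
}

#' @export
print.vf_recording <- function(x, ...) {
  cat(sprintf("<vf_recording %s [%s]> %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, length(x$samples), x$fs, x$duration_s))
  invisible(x)
}

# Stationary Ornstein-Uhlenbeck path sampled at 1/fs, via the exact AR(1)
# discretization; sd is the stationary standard deviation, tau the
# correlation time in seconds. Implemented with stats::filter (C loop).
ou_path <- function(n, fs, sd, tau) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-1 / (fs * tau))
  innov_sd <- sd * sqrt(1 - a^2)
  eps <- rnorm(n, sd = innov_sd)
  eps[1] <- rnorm(1, sd = sd)   # start in the stationary distribution
  as.numeric(stats::filter(eps, a, method = "recursive"))
}

#' Simulate one VF-like recording from a condition template
#'
#' The instantaneous centre frequency follows
#' `f0_start - drop_mag * sigmoid((t - f0_drop_time - 8)/3) + slow wobble + fast
#' wobble`, where the slow wobble is a mean-reverting (Ornstein-Uhlenbeck)
#' process with stationary standard deviation `drift_sd` and ~20 s
#' correlation time, and the fast wobble (correlation time 0.3 s, standard
#' deviation `bandwidth/4`) broadens each short-time spectral peak to the
#' template's instantaneous bandwidth; default templates keep
#' `drift_sd <= bandwidth/4` so the dominant frequency stays inside
#' `f0_start +/- bandwidth`. Before `fork_onset` a single
#' oscillator sits at the centre frequency; afterwards two oscillators at
#' centre +/- `fork_separation/2` share the total power, the split ramping in
#' over `fork_ramp` seconds. Broadband Gaussian noise with power
#' `noise_floor` relative to the oscillator power is added, plus slow
#' independent amplitude modulation per oscillator.
#'
#' @param template a `vf_template`.
#' @param duration_s recording length in seconds (default 360).
#' @param fs sampling rate in Hz (default 1000).
#' @param seed integer seed.
#' @param subject_id id string stored in the recording.
#' @return a `vf_recording` with `round(fs * duration_s)` samples.
#' @export
simulate_recording <- function(template, duration_s = 360, fs = 1000,
                               seed = 0L, subject_id = template$condition) {
  if (!inherits(template, "vf_template")) vf_input_error("template must be a vf_template")
  if (!is.numeric(duration_s) || duration_s <= 0) vf_input_error("duration_s must be > 0")
  if (!is.numeric(fs) || fs <= 0) vf_input_error("fs must be > 0")
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1) / fs
  samples <- with_seed(seed, {
    # transition begins at f0_drop_time: sigmoid centered 8 s later with a
    # 3 s width leaves the pre-drop plateau (< 5% engaged) before that time
    phase_in <- 1 / (1 + exp(-(t - template$f0_drop_time - 8) / 3))
    drop <- template$drop_mag * phase_in
    # early dynamics are nearly common across conditions; the template's
    # terminal bandwidth fades in through the ~50 s transition
    bw_early <- min(template$bandwidth, 1.0)
    bw_t <- bw_early + (template$bandwidth - bw_early) * phase_in
    f_center <- template$f0_start - drop +
      ou_path(n, fs, template$drift_sd, 20) +
      (bw_t / 4) * ou_path(n, fs, 1, 0.3)
    # fork ramp beta(t) in [0, 1]: fraction of the split realized
    beta <- if (is.na(template$fork_onset)) numeric(n) else
      pmin(1, pmax(0, (t - template$fork_onset) / max(template$fork_ramp, 1e-9)))
    f1 <- f_center + beta * template$fork_separation / 2
    f2 <- f_center - beta * template$fork_separation / 2
    A <- template$amplitude
    a1 <- A * sqrt(1 - beta / 2) * (1 + 0.2 * ou_path(n, fs, 1, 10))
    a2 <- A * sqrt(beta / 2) * (1 + 0.2 * ou_path(n, fs, 1, 10))
    ph1 <- 2 * pi * cumsum(f1) / fs + runif(1, 0, 2 * pi)
    ph2 <- 2 * pi * cumsum(f2) / fs + runif(1, 0, 2 * pi)
    noise_sd <- A * sqrt(template$noise_floor / 2)
    a1 * sin(ph1) + a2 * sin(ph2) + rnorm(n, sd = noise_sd)
  })
  new_vf_recording(samples, fs, subject_id, template$condition, duration_s)
}

#' Simulate a cohort of VF recordings
#'
#' Per-subject seeds (and the per-subject ANSB fork onsets) are derived
#' deterministically from the master seed, so the same call always
#' reproduces the same cohort, and any single subject can be regenerated in
#' isolation. The default counts give 27 subjects: 3 training subjects per
#' condition plus a test group of 1 ANSB, 3 flecainide, 2 amiodarone,
#' 3 diltiazem and 3 control subjects.
#'
#' @param counts named integer vector/list mapping condition to subject
#'   count.
#' @param seed master integer seed.
#' @param duration_s,fs forwarded to [simulate_recording()].
#' @return list of `vf_recording` objects with unique subject ids like
#'   `"diltiazem03"`.
#' @export
simulate_cohort <- function(counts = c(control = 6, amiodarone = 5, diltiazem = 6,
                                       flecainide = 6, ansb = 4),
                            seed = 0L, duration_s = 360, fs = 1000) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || !all(names(counts) %in% VF_CONDITIONS))
    vf_input_error("counts must be named with known condition labels")
  if (any(counts < 0)) vf_input_error("counts must be >= 0")
  out <- list()
  for (cond in names(counts)) {
    for (i in seq_len(counts[[cond]])) {
      sid <- sprintf("%s%02d", cond, i)
      sseed <- derive_seed(seed, sid)
      tpl <- make_condition_template(cond, seed = sseed)
      out[[sid]] <- simulate_recording(tpl, duration_s = duration_s, fs = fs,
                                       seed = sseed, subject_id = sid)
    }
  }
  out
}

#' Inject amplitude-clipping artifacts into a recording
#'
#' Emulates analog-to-digital saturation: randomly placed runs are replaced
#' by a constant rail value `+/- rail_fraction * max(|samples|)` (sign taken
#' from the local signal mean). The injected run positions are attached as
#' the `clip_runs` attribute (a data.frame of `start`/`end` sample indices)
#' so restoration can be scored against ground truth.
#'
#' @param recording a `vf_recording`.
#' @param rail_fraction rail level as a fraction of the recording's peak
#'   absolute amplitude, in (0, 1].
#' @param run_rate expected number of clipping runs per minute.
#' @param seed integer seed.
#' @param run_ms two-element numeric range of run lengths in milliseconds.
#' @return a new `vf_recording` with the `clip_runs` attribute.
#' @export
inject_clipping <- function(recording, rail_fraction = 0.5, run_rate = 2,
                            seed = 0L, run_ms = c(30, 80)) {
  if (!inherits(recording, "vf_recording")) vf_input_error("recording must be a vf_recording")
  if (rail_fraction <= 0 || rail_fraction > 1)
    vf_input_error("rail_fraction must be in (0, 1]")
  if (run_rate < 0) vf_input_error("run_rate must be >= 0")
  x <- recording$samples
  n <- length(x)
  runs <- data.frame(start = integer(0), end = integer(0))
  if (run_rate > 0) {
    rail <- rail_fraction * max(abs(x))
    with_seed(derive_seed(seed, "clip"), {
      n_runs <- rpois(1, run_rate * recording$duration_s / 60)
      if (n_runs > 0) {
        lens <- round(runif(n_runs, run_ms[1], run_ms[2]) * recording$fs / 1000)
        starts <- sort(sample.int(n, n_runs))
        for (k in seq_len(n_runs)) {
          i0 <- starts[k]; i1 <- min(n, starts[k] + lens[k] - 1)
          sgn <- if (mean(x[i0:i1]) >= 0) 1 else -1
          x[i0:i1] <- sgn * rail
          runs <- rbind(runs, data.frame(start = i0, end = i1))
        }
      }
    })
  }
  out <- new_vf_recording(x, recording$fs, recording$subject_id,
                          recording$condition, recording$duration_s)
  attr(out, "clip_runs") <- runs
  out
}
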