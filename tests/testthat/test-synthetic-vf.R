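test_that("condition templates encode the per-condition fingerprints", {
  tpls <- lapply(c("control", "amiodarone", "diltiazem", "flecainide", "ansb"),
                 make_condition_template, seed = 0)
  names(tpls) <- vapply(tpls, `[[`, "", "condition")
  for (tpl in tpls) {
    expect_gte(tpl$f0_start, 5); expect_lte(tpl$f0_start, 12)
    expect_gte(tpl$fork_separation, 0)
    expect_gt(tpl$bandwidth, 0)
    expect_gte(tpl$noise_floor, 0); expect_lt(tpl$noise_floor, 1)
  }
  # flecainide never forks and is strictly narrower than every forked template
  expect_true(is.na(tpls$flecainide$fork_onset))
  forked <- tpls[c("amiodarone", "diltiazem", "ansb")]
  for (tpl in forked) {
    expect_false(is.na(tpl$fork_onset))
    expect_lt(tpls$flecainide$bandwidth, tpl$bandwidth)
  }
  # control is the most erratic; diltiazem has the widest fork dispersion
  expect_true(all(tpls$control$drift_sd >
                    vapply(tpls[-1], `[[`, 0, "drift_sd")))
  expect_true(all(tpls$diltiazem$fork_separation >=
                    vapply(forked, `[[`, 0, "fork_separation")))
  expect_error(make_condition_template("placebo"), class = "vflatent_input_error")
})

test_that("templates are deterministic under seed; ANSB fork onset varies", {
  expect_identical(make_condition_template("control", 0),
                   make_condition_template("control", 0))
  onsets <- vapply(1:100, function(s)
    make_condition_template("ansb", s)$fork_onset, 0)
  expect_gt(length(unique(onsets)), 50)
  expect_true(all(onsets >= 60 & onsets <= 120))
})

test_that("simulated recordings have the requested geometry and are seeded", {
  tpl <- make_condition_template("control")
  rec <- simulate_recording(tpl, duration_s = 360, fs = 1000, seed = 3)
  expect_s3_class(rec, "vf_recording")
  expect_length(rec$samples, 360000)
  expect_true(all(is.finite(rec$samples)))
  rec2 <- simulate_recording(tpl, duration_s = 360, fs = 1000, seed = 3)
  expect_identical(rec$samples, rec2$samples)
  expect_error(simulate_recording(tpl, duration_s = 0), class = "vflatent_input_error")
  expect_error(simulate_recording(tpl, fs = -1), class = "vflatent_input_error")
})

test_that("early-window dominant frequency sits in the narrow 5-10 Hz band", {
  rec <- short_recording("control", duration_s = 30, seed = 1)
  w <- window_signal(rec, 2048, 1024)
  df <- vapply(seq_len(nrow(w$windows)), function(i)
    dominant_frequency(welch_psd(w$windows[i, ], 1000)), 0)
  expect_true(all(df >= 5 & df <= 10))
})

test_that("spectral placement: early dominant frequency stays within the template band", {
  for (cond in c("control", "amiodarone", "diltiazem", "flecainide", "ansb")) {
    tpl <- make_condition_template(cond, seed = 11)
    rec <- simulate_recording(tpl, seed = 11)
    w <- window_signal(rec, 2048, 1024)
    early <- which(w$t_start + 2.048 <= 50)
    df <- vapply(early, function(i)
      dominant_frequency(welch_psd(w$windows[i, ], 1000)), 0)
    frac <- mean(df >= tpl$f0_start - tpl$bandwidth &
                   df <= tpl$f0_start + tpl$bandwidth)
    expect_gte(frac, 0.9)
  }
})

test_that("forked conditions split into two resolvable spectral peaks", {
  count_peaks <- function(w) {
    v <- as.numeric(low_band_vector(welch_psd(w, 1000), 16))
    pk <- which(diff(sign(diff(v))) == -2) + 1
    sum(v[pk] > 0.2 * max(v))
  }
  for (cond in c("amiodarone", "diltiazem")) {
    tpl <- make_condition_template(cond, seed = 7)
    rec <- simulate_recording(tpl, seed = 7)
    w <- window_signal(rec, 2048, 1024)
    pre <- which(w$t_start + 2.048 < tpl$fork_onset)
    post <- which(w$t_start > tpl$fork_onset + tpl$fork_ramp + 5)
    n_pre <- mean(vapply(pre, function(i) count_peaks(w$windows[i, ]), 0))
    n_post <- mean(vapply(post, function(i) count_peaks(w$windows[i, ]), 0))
    expect_gt(n_post, n_pre)
  }
})

test_that("post-fork periodogram peaks are separated by the template dispersion", {
  tpl <- make_condition_template("amiodarone")
  rec <- simulate_recording(tpl, seed = 2)
  w <- window_signal(rec, 2048, 1024)
  i <- which(w$t_start > tpl$fork_onset + tpl$fork_ramp + 20)[1]
  p <- welch_psd(w$windows[i, ], 1000, segment = 2048, seg_overlap = 0, nfft = 2048)
  v <- as.numeric(low_band_vector(p, 16))
  fr <- attr(low_band_vector(p, 16), "freqs")
  pk <- which(diff(sign(diff(v))) == -2) + 1
  pk <- pk[order(v[pk], decreasing = TRUE)][1:2]
  bin <- 1000 / 2048
  expect_lt(abs(abs(diff(fr[pk])) - tpl$fork_separation), bin + 1e-9)
})

test_that("cohorts have the requested composition and unique, seeded subjects", {
  small <- simulate_cohort(counts = c(control = 3, amiodarone = 3, diltiazem = 3,
                                      flecainide = 3, ansb = 3),
                           seed = 1, duration_s = 2)
  expect_length(small, 15)
  expect_false(anyDuplicated(vapply(small, `[[`, "", "subject_id")) > 0)
  conds <- c("control", "amiodarone", "diltiazem", "flecainide", "ansb")
  expect_equal(unname(table(vapply(small, `[[`, "", "condition"))[conds]),
               rep(3L, 5), ignore_attr = TRUE)
  again <- simulate_cohort(counts = c(control = 3, amiodarone = 3, diltiazem = 3,
                                      flecainide = 3, ansb = 3),
                           seed = 1, duration_s = 2)
  expect_identical(lapply(small, `[[`, "samples"), lapply(again, `[[`, "samples"))
  # the published test-group composition
  test_counts <- c(ansb = 1, flecainide = 3, amiodarone = 2, diltiazem = 3, control = 3)
  tc <- simulate_cohort(counts = test_counts, seed = 2, duration_s = 2)
  expect_length(tc, 12)
  expect_error(simulate_cohort(counts = c(foo = 2)), class = "vflatent_input_error")
})

test_that("clipping injection saturates flat runs at the rail and is invertible bookkeeping", {
  rec <- short_recording("control", duration_s = 60, seed = 5)
  expect_identical(inject_clipping(rec, run_rate = 0)$samples, rec$samples)
  clip <- inject_clipping(rec, rail_fraction = 0.5, run_rate = 6, seed = 1)
  runs <- attr(clip, "clip_runs")
  expect_gt(nrow(runs), 0)
  rail <- 0.5 * max(abs(rec$samples))
  for (k in seq_len(nrow(runs))) {
    seg <- clip$samples[runs$start[k]:runs$end[k]]
    expect_equal(stats::var(seg), 0)           # locally zero variance
    expect_equal(abs(seg[1]), rail)
  }
  expect_lte(max(abs(clip$samples)), max(abs(rec$samples)))
  expect_error(inject_clipping(rec, rail_fraction = 1.5), class = "vflatent_input_error")
})
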