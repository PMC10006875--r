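test_that("psychoacoustic scale conversions match their closed forms and are monotone", {
  expect_equal(scale_convert(0, "mel"), 0)
  expect_equal(scale_convert(700, "mel"), 2595 * log10(2), tolerance = 1e-12)
  expect_equal(scale_convert(1000, "erb"), 21.4 * log10(1 + 4.37), tolerance = 1e-12)
  expect_equal(scale_convert(123, "linear"), 123)
  grid <- seq(0, 500, by = 0.5)
  for (sc in c("mel", "bark", "erb"))
    expect_true(all(diff(scale_convert(grid, sc)) > 0))
  expect_error(scale_convert(-1, "mel"), class = "vflatent_input_error")
})

test_that("filterbanks tile the band with normalized triangles", {
  freqs <- (0:2048) * 1000 / 4096
  fb <- build_filterbank("linear", 4, 0, 50, freqs)
  expect_equal(fb$centers, c(10, 20, 30, 40), tolerance = 1e-9)
  expect_equal(dim(fb$weights), c(4, length(freqs)))
  expect_equal(rowSums(fb$weights), rep(1, 4), tolerance = 1e-12)
  # interior coverage: every interior bin in (0, 50) has weight somewhere
  interior <- freqs > 0.5 & freqs < 49.5
  expect_true(all(colSums(fb$weights)[interior] > 0))
  # no band leaks outside [f_low, f_high]
  outside <- freqs > 50.001
  expect_true(all(fb$weights[, outside] == 0))
  # a single nonzero FFT bin only excites the triangles that cover it
  x <- numeric(length(freqs)); x[which.min(abs(freqs - 35))] <- 1
  resp <- band_energies(x, fb)
  expect_true(all(resp[c(1, 2)] == 0) && any(resp[c(3, 4)] > 0))
  # ERB-256 on the 50 Hz cap: strictly increasing centers, all below the cap
  fb256 <- build_filterbank("erb", 256, 0, 50, freqs)
  expect_length(fb256$centers, 256)
  expect_true(all(diff(fb256$centers) > 0))
  expect_true(all(fb256$centers > 0 & fb256$centers < 50))
  expect_equal(rowSums(fb256$weights), rep(1, 256), tolerance = 1e-12)
  flat <- band_energies(rep(3, length(freqs)), fb)
  expect_equal(flat, rep(3, 4), tolerance = 1e-12)
  expect_error(band_energies(1:5, fb), class = "vflatent_input_error")
})

test_that("descriptors agree with closed forms on point masses and symmetric pairs", {
  f <- c(5, 10, 15, 20, 25)
  # two equal bands at 10 and 20 Hz
  d <- descriptor_vector(c(0, 1, 0, 1, 0), f)
  expect_equal(unname(d["centroid"]), 15)
  expect_equal(unname(d["spread"]), 5)
  expect_equal(unname(d["skewness"]), 0)
  expect_equal(unname(d["kurtosis"]), 1)
  # flatness is over band values incl. zeros -> 0 here; on the two-band
  # sub-spectrum it is 1
  d2 <- descriptor_vector(c(1, 1), c(10, 20))
  expect_equal(unname(d2["flatness"]), 1)
  expect_equal(unname(d2["entropy"]), 1)
  # point mass at 7 Hz among N bands
  N <- 8
  s <- numeric(N); s[3] <- 2
  fr <- c(3, 5, 7, 9, 11, 13, 15, 17)
  d3 <- descriptor_vector(s, fr)
  expect_equal(unname(d3["spread"]), 0)
  expect_equal(unname(d3["rolloff"]), 7)
  expect_equal(unname(d3["crest"]), N)
  expect_error(descriptor_vector(numeric(4), 1:4),
               class = "vflatent_degenerate_error")
})

test_that("all eleven descriptors match the brute-force oracle on random spectra", {
  set.seed(42)
  n_bands <- 32
  f <- sort(runif(n_bands, 0.5, 50))
  prev <- NULL
  for (i in 1:200) {
    s <- runif(n_bands, 0, 1)^2 + 1e-6
    got <- descriptor_vector(s, f, prev)
    want <- oracle_descriptors(s, f, prev)
    expect_lt(max(abs(got - want)), 1e-9)
    prev <- s
  }
})

test_that("descriptor moments are shift covariant in frequency", {
  set.seed(7)
  f <- sort(runif(16, 1, 40))
  s <- runif(16, 0.1, 2)
  a <- descriptor_vector(s, f)
  b <- descriptor_vector(s, f + 5)
  expect_equal(unname(b["centroid"] - a["centroid"]), 5, tolerance = 1e-9)
  for (nm in c("spread", "skewness", "kurtosis"))
    expect_equal(unname(a[nm]), unname(b[nm]), tolerance = 1e-9)
})

test_that("audio feature matrices have 11 named columns and restart flux per subject", {
  rec1 <- short_recording("control", duration_s = 10, seed = 1)
  rec2 <- short_recording("flecainide", duration_s = 10, seed = 2)
  ws <- bind_windowsets(list(window_signal(rec1, 2048, 1024),
                             window_signal(rec2, 2048, 1024)))
  M <- audio_feature_matrix(ws)
  expect_equal(ncol(M), 11)
  expect_equal(colnames(M)[1:3], c("centroid", "spread", "skewness"))
  first_of_each <- which(!duplicated(ws$subject_ids))
  expect_true(all(M[first_of_each, "flux"] == 0))
  expect_true(all(M[-first_of_each, "flux"] > 0))
})

test_that("generated diltiazem and flecainide recordings differ in mean spectral spread", {
  dil <- simulate_recording(make_condition_template("diltiazem"), seed = 4)
  fle <- simulate_recording(make_condition_template("flecainide"), seed = 4)
  spread_of <- function(r) {
    ws <- window_signal(r, 2048, 1024)
    mean(audio_feature_matrix(ws)[, "spread"])
  }
  expect_false(isTRUE(all.equal(spread_of(dil), spread_of(fle), tolerance = 1e-3)))
})

test_that("z-scoring self-normalizes and reuses training statistics on test data", {
  set.seed(3)
  X <- matrix(rnorm(200, mean = 5, sd = 2), 50, 4)
  Z <- zscore_normalize(X)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
  shifted <- X + 10
  Zs <- zscore_normalize(shifted, stats = attr(Z, "stats"))
  expect_true(all(abs(colMeans(Zs)) > 1))
  const <- cbind(X[, 1:3], 7)
  expect_error(zscore_normalize(const), class = "vflatent_degenerate_error")
})

test_that("whole-sequence tracks have the published dimensionality", {
  rec <- simulate_recording(make_condition_template("diltiazem"), seed = 3)
  tr <- whole_sequence_tracks(rec)
  expect_equal(dim(tr$tracks), c(11, 1796))
  expect_length(concat_tracks(tr), 19756)
  expect_length(concat_tracks(tr, 1:5), 8980)
  expect_length(concat_tracks(tr, c("spread", "slope")), 2 * 1796)
  short <- short_recording(duration_s = 0.5, seed = 1)
  expect_error(whole_sequence_tracks(short), class = "vflatent_input_error")
})
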