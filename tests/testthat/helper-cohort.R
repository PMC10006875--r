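# Shared fixtures: the default 27-subject synthetic cohort and the heavy
# windowed experiments are computed once per test session and reused.
.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort))
    .fixture_cache$cohort <- simulate_cohort(seed = 0)
  .fixture_cache$cohort
}

cached_experiment <- function(variant, fspace, mode) {
  key <- paste(variant, fspace, mode, sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- run_windowed_experiment(
      default_cohort(),
      experiment_config(variant, fspace, mode, seed = 0))
  .fixture_cache[[key]]
}

# Short single-subject recording for cheap unit tests.
short_recording <- function(condition = "control", duration_s = 60, seed = 5) {
  simulate_recording(make_condition_template(condition, seed = seed),
                     duration_s = duration_s, seed = seed)
}

rms_error <- function(a, b) sqrt(mean((a - b)^2))
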