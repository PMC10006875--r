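#' @keywords internal
"_PACKAGE"

# Classed error helpers so callers and tests can distinguish bad inputs from
# genuine bugs.
vf_input_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("vflatent_input_error", "vflatent_error")))
}

vf_config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("vflatent_config_error", "vflatent_error")))
}

vf_degenerate_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("vflatent_degenerate_error", "vflatent_error")))
}

#' Derive a reproducible child seed from a master seed and a tag
#'
#' All randomized stages draw their RNG seed through this helper so that a
#' single master seed makes the whole pipeline reproducible while keeping the
#' stages statistically independent. The result always fits in a 32-bit
#' signed integer.
#'
#' @param master integer master seed.
#' @param tag character tag naming the consumer (e.g. a subject id).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  if (!is.numeric(master) || length(master) != 1 || !is.finite(master))
    vf_input_error("master seed must be a single finite number")
  codes <- utf8ToInt(as.character(tag))
  # 64-bit-safe polynomial hash folded into the 31-bit range
  h <- (abs(master) %% 2147483647)
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
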