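# Typed error conditions. Every user-facing failure mode raises a condition
# whose class starts with "lnqdetect_", so callers (and tests) can catch the
# category rather than match message text.

abort_lnq <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "lnqdetect_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
stop_range <- function(msg) abort_lnq(msg, "lnqdetect_range_error")
stop_degenerate <- function(msg) abort_lnq(msg, "lnqdetect_degenerate_error")
stop_infeasible <- function(msg) abort_lnq(msg, "lnqdetect_infeasible_error")
stop_config <- function(msg) abort_lnq(msg, "lnqdetect_config_error")
stop_schema <- function(msg) abort_lnq(msg, "lnqdetect_schema_error")
stop_data <- function(msg) abort_lnq(msg, "lnqdetect_data_error")
stop_no_split <- function(msg) abort_lnq(msg, "lnqdetect_no_split_error")
stop_spec <- function(msg) abort_lnq(msg, "lnqdetect_spec_error")

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state
# afterwards so package functions never disturb the global random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# round-half-up, the fixed rounding rule for every gray-level mapping
round_half_up <- function(x) floor(x + 0.5)

# x first: pmin/pmax take shape attributes from their first argument
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
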