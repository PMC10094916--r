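# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero upwards
#'
#' Gray-level conversion uses round-half-up (`floor(x + 0.5)`), not banker's
#' rounding, so that exact midpoints such as 127.5 map deterministically to
#' the upper level.
#'
#' @param x numeric vector.
#' @return `floor(x + 0.5)`.
#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# Classed errors so callers and tests can distinguish failure modes.
hs_stop <- function(msg, class, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(class, "hyperskin_error")))
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers a user's random stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
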