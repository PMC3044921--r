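#' Round half away from zero
#'
#' Commercial rounding used for display values: 0.5 always moves away from
#' zero, so 0.125 -> 0.13 and 4.5 -> 5 (unlike [base::round()]'s banker's
#' rounding). Published disagreement indices and medians follow this
#' convention.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(0.125, 2) # 0.13
#' round_half_away(4.5, 0)   # 5
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  # nudge by epsilon scaled to x to defeat binary representation error
  # (0.85 is stored slightly below 0.85; plain trunc would round it down)
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps) * abs(x)) / scale
}

# Evaluate `expr` under seed `seed` without disturbing the caller's RNG
# stream. All stochastic operations in the package run through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
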