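#' Bounded integer rating scale
#'
#' The appropriateness method rates each item on a bounded integer scale;
#' the canonical instrument is the 9-point scale running 0 (completely
#' inappropriate) to 8 (extremely important). The scale carries the two
#' median thresholds used to classify items: a median at or above
#' `appropriate_threshold` makes an item appropriate, a median below
#' `inappropriate_threshold` makes it inappropriate, anything between is
#' uncertain. The midpoint, (minimum + maximum) / 2, anchors the asymmetry
#' index of the disagreement calculation.
#'
#' @param minimum,maximum integer scale bounds, `minimum < maximum`.
#' @param appropriate_threshold median at or above this is "appropriate".
#' @param inappropriate_threshold median strictly below this is
#'   "inappropriate"; must be less than `appropriate_threshold`.
#' @return an object of class `rating_scale`: a list with fields
#'   `minimum`, `maximum`, `midpoint`, `appropriate_threshold`,
#'   `inappropriate_threshold`.
#' @export
#' @examples
#' rating_scale()                    # the default 0-8 scale, midpoint 4
#' rating_scale(1, 9, 7, 4)          # a 1-9 variant, midpoint 5
rating_scale <- function(minimum = 0L, maximum = 8L,
                         appropriate_threshold = 6,
                         inappropriate_threshold = 3) {
  minimum <- as.integer(minimum)
  maximum <- as.integer(maximum)
  if (!is.finite(minimum) || !is.finite(maximum) || minimum >= maximum)
    stop_input("rating scale requires minimum < maximum (got %s, %s)",
               minimum, maximum)
  if (!(inappropriate_threshold < appropriate_threshold))
    stop_input("inappropriate_threshold (%s) must be below appropriate_threshold (%s)",
               inappropriate_threshold, appropriate_threshold)
  structure(
    list(minimum = minimum, maximum = maximum,
         midpoint = (minimum + maximum) / 2,
         appropriate_threshold = appropriate_threshold,
         inappropriate_threshold = inappropriate_threshold),
    class = "rating_scale")
}

#' @export
print.rating_scale <- function(x, ...) {
  cat(sprintf(
    "<rating_scale> %d..%d (midpoint %.1f); appropriate if median >= %s, inappropriate if < %s\n",
    x$minimum, x$maximum, x$midpoint,
    format(x$appropriate_threshold), format(x$inappropriate_threshold)))
  invisible(x)
}

scale_points <- function(scale) seq(scale$minimum, scale$maximum)

assert_rating_scale <- function(scale) {
  if (!inherits(scale, "rating_scale"))
    stop_input("expected a rating_scale object")
  invisible(scale)
}
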