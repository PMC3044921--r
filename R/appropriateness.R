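#' Engine configuration for the appropriateness statistics
#'
#' Parameters of the disagreement calculation. `ipr_r` is the
#' interpercentile range that signals disagreement when ratings are
#' perfectly symmetric about the scale midpoint, and `cfa` the correction
#' factor applied to the asymmetry index; the calibrated values for
#' 9-point scales, 2.35 and 1.5, reproduce the classic panel-size-bound
#' definitions of disagreement while applying to panels of any size.
#' `lower_p` and `upper_p` are the percentile pair spanning the IPR (30th
#' and 70th by default).
#'
#' @param ipr_r required interpercentile range under perfect symmetry
#'   (> 0; default 2.35).
#' @param cfa correction factor for asymmetry (>= 0; default 1.5).
#' @param lower_p,upper_p probabilities with `0 < lower_p < upper_p < 1`
#'   (defaults 0.30, 0.70).
#' @param quantile_method `"linear_interpolation"` (sorted values x(1..n),
#'   h = (n-1)p + 1, interpolate between x(floor(h)) and x(floor(h)+1)) or
#'   `"nearest_rank"` (x(ceiling(n p))).
#' @param display_decimals_di decimals used when displaying the
#'   disagreement index (default 2).
#' @param min_panel floor on per-item responses below which results are
#'   flagged unstable (computed regardless; default 7).
#' @param demote_disagreement if `TRUE`, an item with panel disagreement
#'   is demoted to "uncertain" whatever its median (classic-RAND style);
#'   off by default -- the median alone decides the category.
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(ipr_r = 2.35, cfa = 1.5,
                          lower_p = 0.30, upper_p = 0.70,
                          quantile_method = c("linear_interpolation", "nearest_rank"),
                          display_decimals_di = 2L, min_panel = 7L,
                          demote_disagreement = FALSE) {
  quantile_method <- match.arg(quantile_method)
  if (!(ipr_r > 0)) stop_input("ipr_r must be positive")
  if (cfa < 0) stop_input("cfa must be non-negative")
  if (!(0 < lower_p && lower_p < upper_p && upper_p < 1))
    stop_input("need 0 < lower_p < upper_p < 1")
  structure(
    list(ipr_r = ipr_r, cfa = cfa, lower_p = lower_p, upper_p = upper_p,
         quantile_method = quantile_method,
         display_decimals_di = as.integer(display_decimals_di),
         min_panel = as.integer(min_panel),
         demote_disagreement = isTRUE(demote_disagreement)),
    class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf(
    "<engine_config> IPRr=%.2f CFA=%.2f percentiles %.0f/%.0f (%s), DI shown to %d dp\n",
    x$ipr_r, x$cfa, 100 * x$lower_p, 100 * x$upper_p, x$quantile_method,
    x$display_decimals_di))
  invisible(x)
}

#' Percentile of a rating multiset
#'
#' Small-sample quantile under one of two deterministic conventions.
#' Linear interpolation places the percentile at rank h = (n-1)p + 1 of
#' the sorted values and interpolates (the default of [stats::quantile()],
#' type 7); nearest rank returns the value at rank ceiling(n p) (type 1).
#'
#' @param ratings non-empty numeric vector.
#' @param p probability in `[0, 1]`.
#' @param method `"linear_interpolation"` or `"nearest_rank"`.
#' @return the percentile, always within `range(ratings)`.
#' @export
#' @examples
#' rating_percentile(c(0:8, 8), 0.3)  # h = 3.7 -> 2.7
rating_percentile <- function(ratings,
                              p,
                              method = c("linear_interpolation", "nearest_rank")) {
  method <- match.arg(method)
  if (!length(ratings)) stop_input("cannot take a percentile of no ratings")
  if (anyNA(ratings)) stop_input("ratings contain NA")
  if (!(p >= 0 && p <= 1)) stop_input("p must be in [0, 1]")
  type <- if (method == "linear_interpolation") 7L else 1L
  unname(quantile(as.numeric(ratings), probs = p, type = type, names = FALSE))
}

#' Median of a rating multiset
#'
#' Middle order statistic (odd n) or the mean of the two middle order
#' statistics (even n); with an even panel the median of integer ratings
#' may end in .5.
#'
#' @param ratings non-empty numeric vector.
#' @return the sample median.
#' @export
rating_median <- function(ratings) {
  if (!length(ratings)) stop_input("cannot take the median of no ratings")
  if (anyNA(ratings)) stop_input("ratings contain NA")
  median(as.numeric(ratings))
}

#' Classify an item's appropriateness from its median
#'
#' An item is appropriate when its median rating reaches the scale's
#' upper threshold (>= 6 on the default 0--8 scale), inappropriate when
#' the median falls below the lower threshold (< 3), and uncertain in
#' between.
#'
#' @param median item median rating, within the scale bounds.
#' @param scale a [rating_scale()].
#' @return one of `"appropriate"`, `"uncertain"`, `"inappropriate"`.
#' @export
classify_appropriateness <- function(median, scale = rating_scale()) {
  assert_rating_scale(scale)
  if (anyNA(median)) stop_input("median is NA")
  if (any(median < scale$minimum | median > scale$maximum))
    stop_input("median %s outside scale %d..%d",
               median[1L], scale$minimum, scale$maximum)
  ifelse(median >= scale$appropriate_threshold, "appropriate",
         ifelse(median < scale$inappropriate_threshold, "inappropriate",
                "uncertain"))
}

#' Classify panel disagreement from the disagreement index
#'
#' There is no disagreement when the index is below 1.0; an index of 1.0
#' or more (the IPR at or beyond the item's IPRAS threshold) is
#' disagreement.
#'
#' @param disagreement_index non-negative disagreement index.
#' @return logical: `TRUE` when the panel disagreed.
#' @export
classify_disagreement <- function(disagreement_index) {
  if (anyNA(disagreement_index)) stop_input("disagreement index is NA")
  if (any(disagreement_index < 0)) stop_input("disagreement index must be >= 0")
  disagreement_index >= 1.0
}

#' Appropriateness statistics from printed summary values
#'
#' Runs the statistic chain from an item's median and centile pair alone,
#' as needed when only a published summary table is available: IPR =
#' p70 - p30; the IPR central point IPRCP = (p30 + p70) / 2; asymmetry
#' index AI = |midpoint - IPRCP|; IPRAS = IPRr + AI x CFA; disagreement
#' index DI = IPR / IPRAS; then both classifications. The response count
#' is unknown in this mode (`n` is `NA` and the result is marked
#' summary-only).
#'
#' @param item_id item label.
#' @param median,p30,p70 printed summary statistics, within the scale,
#'   with `p30 <= p70`.
#' @param scale a [rating_scale()].
#' @param config an [engine_config()].
#' @param stage round label.
#' @return an object of class `item_statistics` (see [analyze_item()]).
#' @export
#' @examples
#' s <- statistics_from_percentiles("1a", 6.0, 6, 7)
#' round_half_away(s$disagreement_index, 2)  # 0.16
statistics_from_percentiles <- function(item_id, median, p30, p70,
                                        scale = rating_scale(),
                                        config = engine_config(),
                                        stage = "1") {
  assert_rating_scale(scale)
  vals <- c(median = median, p30 = p30, p70 = p70)
  if (anyNA(vals)) stop_input("item %s: summary statistics contain NA", item_id)
  out_of_scale <- vals < scale$minimum | vals > scale$maximum
  if (any(out_of_scale))
    stop_input("item %s: %s = %s outside scale %d..%d", item_id,
               names(vals)[out_of_scale][1L], vals[out_of_scale][1L],
               scale$minimum, scale$maximum)
  if (p30 > p70)
    stop_input("item %s: p30 (%s) exceeds p70 (%s)", item_id, p30, p70)
  build_statistics(item_id, stage, n = NA_integer_, median = median,
                   p30 = p30, p70 = p70, scale = scale, config = config,
                   summary_only = TRUE)
}

build_statistics <- function(item_id, stage, n, median, p30, p70,
                             scale, config, summary_only, unstable = FALSE) {
  ipr <- p70 - p30
  iprcp <- (p30 + p70) / 2
  ai <- abs(scale$midpoint - iprcp)
  ipras <- config$ipr_r + ai * config$cfa
  di <- ipr / ipras
  appropriateness <- classify_appropriateness(median, scale)
  disagreement <- classify_disagreement(di)
  if (config$demote_disagreement && disagreement)
    appropriateness <- "uncertain"
  structure(
    list(item_id = item_id, stage = stage, n = n, median = median,
         p30 = p30, p70 = p70, ipr = ipr, iprcp = iprcp, ai = ai,
         ipras = ipras, disagreement_index = di,
         appropriateness = appropriateness, disagreement = disagreement,
         summary_only = summary_only, unstable = unstable,
         config = config, scale = scale),
    class = "item_statistics")
}

#' @export
print.item_statistics <- function(x, ...) {
  cat(sprintf(
    "<item_statistics> item %s (stage %s%s): median %.1f, centiles (%s, %s), DI %s -> %s%s%s\n",
    x$item_id, x$stage,
    if (is.na(x$n)) ", summary-only" else sprintf(", n=%d", x$n),
    x$median, format(x$p30), format(x$p70),
    format(round_half_away(x$disagreement_index, x$config$display_decimals_di)),
    x$appropriateness,
    if (x$disagreement) ", DISAGREEMENT" else "",
    if (x$unstable) ", unstable (small panel)" else ""))
  invisible(x)
}

#' Full appropriateness analysis of one item
#'
#' Computes the complete statistic chain from an item's raw rating
#' multiset: median, the configured centile pair, IPR, IPRCP, asymmetry
#' index, IPRAS, disagreement index, and the appropriateness and
#' disagreement verdicts. Full precision is kept internally; rounding is
#' applied only when results are displayed or written.
#'
#' @param item an [item_ratings()] with at least one response.
#' @param scale a [rating_scale()]; defaults to the item's own scale.
#' @param config an [engine_config()].
#' @return an object of class `item_statistics`.
#' @export
#' @examples
#' analyze_item(item_ratings("x", c(rep(0, 8), rep(8, 8))))
analyze_item <- function(item, scale = item$scale, config = engine_config()) {
  stopifnot(inherits(item, "item_ratings"))
  assert_rating_scale(scale)
  if (!item$n_responses)
    stop_input("item %s has no responses to analyze", item$item_id)
  r <- item$ratings
  build_statistics(
    item$item_id, item$stage, n = item$n_responses,
    median = rating_median(r),
    p30 = rating_percentile(r, config$lower_p, config$quantile_method),
    p70 = rating_percentile(r, config$upper_p, config$quantile_method),
    scale = scale, config = config, summary_only = FALSE,
    unstable = item$n_responses < config$min_panel)
}

#' Analyze every item of a round
#'
#' @param round a [panel_round()].
#' @param config an [engine_config()].
#' @return a data frame of class `round_results`, one row per item in the
#'   round's order, with columns `item`, `stage`, `n`, `median`, `p30`,
#'   `p70`, `ipr`, `iprcp`, `ai`, `ipras`, `disagreement_index`,
#'   `appropriateness`, `disagreement`, `unstable` (all values full
#'   precision; see [write_results()] for display rounding).
#' @export
analyze_round <- function(round, config = engine_config()) {
  stopifnot(inherits(round, "panel_round"))
  rows <- lapply(round$items, function(it)
    statistics_row(analyze_item(it, round$scale, config)))
  out <- do.call(rbind, rows) %||% statistics_row(NULL)
  rownames(out) <- NULL
  class(out) <- c("round_results", "data.frame")
  out
}

statistics_row <- function(s) {
  if (is.null(s)) {
    return(data.frame(
      item = character(), stage = character(), n = integer(),
      median = numeric(), p30 = numeric(), p70 = numeric(), ipr = numeric(),
      iprcp = numeric(), ai = numeric(), ipras = numeric(),
      disagreement_index = numeric(), appropriateness = character(),
      disagreement = logical(), unstable = logical(),
      stringsAsFactors = FALSE))
  }
  data.frame(
    item = s$item_id, stage = s$stage, n = s$n, median = s$median,
    p30 = s$p30, p70 = s$p70, ipr = s$ipr, iprcp = s$iprcp, ai = s$ai,
    ipras = s$ipras, disagreement_index = s$disagreement_index,
    appropriateness = s$appropriateness, disagreement = s$disagreement,
    unstable = s$unstable, stringsAsFactors = FALSE)
}

#' Recompute the statistic chain from a published summary table
#'
#' Summary-only analysis with a built-in consistency check. Input is a
#' data frame (or CSV read by the caller) with columns `item`, `median`,
#' `p30`, `p70` and optionally `stage`, `appropriateness` and
#' `disagreement_index` as printed. Each row is run through
#' [statistics_from_percentiles()]; where printed columns exist they are
#' compared with the recomputed values -- a printed disagreement index
#' differing from the recomputed one at display precision, or a printed
#' category contradicting the median rule, flags the row. Rows with
#' `p30 > p70` are recorded as row-level errors and skipped, the run
#' continues.
#'
#' @param summaries data frame of printed per-item summaries.
#' @param scale a [rating_scale()].
#' @param config an [engine_config()].
#' @return a data frame like [analyze_round()]'s (with `n` all `NA`), plus
#'   columns `di_printed`, `di_consistent`, `appropriateness_printed`,
#'   `appropriateness_consistent`, `flagged`, `row_error`.
#' @export
analyze_summaries <- function(summaries, scale = rating_scale(),
                              config = engine_config()) {
  stopifnot(is.data.frame(summaries))
  need <- c("item", "median", "p30", "p70")
  if (!all(need %in% names(summaries)))
    stop_input("summary table needs columns %s", paste(need, collapse = ", "))
  has_stage <- "stage" %in% names(summaries)
  has_di <- "disagreement_index" %in% names(summaries)
  has_app <- "appropriateness" %in% names(summaries)
  dd <- config$display_decimals_di
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    r <- summaries[i, ]
    stage <- if (has_stage) as.character(r$stage) else "1"
    s <- tryCatch(
      statistics_from_percentiles(as.character(r$item), as.numeric(r$median),
                                  as.numeric(r$p30), as.numeric(r$p70),
                                  scale, config, stage = stage),
      error = function(e) e)
    if (inherits(s, "error")) {
      out <- statistics_row(NULL)[NA_integer_, ]
      out$item <- as.character(r$item); out$stage <- stage
      out$median <- as.numeric(r$median)
      out$p30 <- as.numeric(r$p30); out$p70 <- as.numeric(r$p70)
      out$row_error <- conditionMessage(s)
    } else {
      out <- statistics_row(s)
      out$row_error <- NA_character_
    }
    out$di_printed <- if (has_di) as.numeric(r$disagreement_index) else NA_real_
    out$appropriateness_printed <-
      if (has_app) tolower(as.character(r$appropriateness)) else NA_character_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- is.na(out$row_error)
  out$di_consistent <- ifelse(
    ok & !is.na(out$di_printed),
    round_half_away(out$disagreement_index, dd) ==
      round_half_away(out$di_printed, dd),
    NA)
  out$appropriateness_consistent <- ifelse(
    ok & !is.na(out$appropriateness_printed),
    out$appropriateness == out$appropriateness_printed,
    NA)
  # `flagged` is the numeric consistency verdict (DI chain); a printed
  # category contradicting the median rule is reported separately via
  # appropriateness_consistent so the two kinds of anomaly stay distinct.
  out$flagged <- !ok | (!is.na(out$di_consistent) & !out$di_consistent)
  out$unstable <- NULL
  class(out) <- c("round_results", "data.frame")
  out
}
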