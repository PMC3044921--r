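#' One item's panel ratings
#'
#' Container for the multiset of rater scores an item received in one
#' round. Missing ratings are simply absent: an item's statistics are
#' computed from its observed responses only (per-item deletion), which
#' is why `n_responses` may fall below `n_raters_invited`.
#'
#' @param item_id item label, e.g. `"1a"` or `"2"`.
#' @param ratings integer vector of scores, each within the scale bounds.
#' @param scale a [rating_scale()].
#' @param stage round label (default `"1"`).
#' @param n_raters_invited number of raters asked; defaults to
#'   `length(ratings)`.
#' @return an object of class `item_ratings`.
#' @export
#' @examples
#' item_ratings("1a", c(6, 6, 7, 7, 8))
item_ratings <- function(item_id, ratings, scale = rating_scale(),
                         stage = "1", n_raters_invited = length(ratings)) {
  assert_rating_scale(scale)
  item_id <- as.character(item_id)
  if (length(item_id) != 1L || is.na(item_id) || !nzchar(item_id))
    stop_input("item_id must be a single non-empty label")
  ratings <- as.numeric(ratings)
  if (anyNA(ratings))
    stop_input("item %s: NA ratings are not allowed; omit missing cells instead",
               item_id)
  if (any(ratings != round(ratings)))
    stop_input("item %s: ratings must be integers", item_id)
  bad <- ratings < scale$minimum | ratings > scale$maximum
  if (any(bad))
    stop_input("item %s: rating %s outside scale %d..%d",
               item_id, ratings[which(bad)[1L]], scale$minimum, scale$maximum)
  if (n_raters_invited < length(ratings))
    stop_input("item %s: n_raters_invited (%d) below number of responses (%d)",
               item_id, n_raters_invited, length(ratings))
  structure(
    list(item_id = item_id, stage = as.character(stage),
         ratings = as.integer(ratings),
         n_raters_invited = as.integer(n_raters_invited),
         n_responses = length(ratings), scale = scale),
    class = "item_ratings")
}

#' @export
print.item_ratings <- function(x, ...) {
  cat(sprintf("<item_ratings> item %s (stage %s): %d/%d responses: %s\n",
              x$item_id, x$stage, x$n_responses, x$n_raters_invited,
              paste(sort(x$ratings), collapse = " ")))
  invisible(x)
}

#' A round of panel ratings
#'
#' An ordered collection of [item_ratings()] sharing one scale, i.e. one
#' rating round of a consensus study.
#'
#' @param items list of `item_ratings` objects with unique item ids.
#' @param scale a [rating_scale()]; every item must use it.
#' @param stage round label.
#' @return an object of class `panel_round`.
#' @export
panel_round <- function(items, scale = rating_scale(), stage = "1") {
  assert_rating_scale(scale)
  if (!is.list(items) || !all(vapply(items, inherits, TRUE, "item_ratings")))
    stop_input("items must be a list of item_ratings objects")
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids))
    stop_input("duplicate item id in round: %s", ids[duplicated(ids)][1L])
  names(items) <- ids
  structure(list(stage = as.character(stage), items = items, scale = scale),
            class = "panel_round")
}

#' @export
print.panel_round <- function(x, ...) {
  cat(sprintf("<panel_round> stage %s: %d items on scale %d..%d\n",
              x$stage, length(x$items), x$scale$minimum, x$scale$maximum))
  invisible(x)
}

#' @export
length.panel_round <- function(x) length(x$items)

#' Read a panel rating table from CSV
#'
#' Two dialects are accepted. Long form (canonical) has columns
#' `item`, `rater`, `rating`, one row per observed rating; an optional
#' `stage` column must be constant. Wide form has one row per rater, a
#' `rater` column, and one column per item. In both forms blank cells are
#' missing responses and are dropped, never imputed.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param format `"long"` (default) or `"wide"`.
#' @param scale a [rating_scale()] used for validation.
#' @param stage round label applied when the file carries none.
#' @return a validated [panel_round()].
#' @export
read_ratings <- function(path, format = c("long", "wide"),
                         scale = rating_scale(), stage = "1") {
  format <- match.arg(format)
  assert_rating_scale(scale)
  if (!file.exists(path)) stop_input("ratings file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character", fileEncoding = "UTF-8")
  if (format == "long") {
    need <- c("item", "rater", "rating")
    if (!all(need %in% names(df)))
      stop_input("long-form ratings need columns item, rater, rating; got: %s",
                 paste(names(df), collapse = ", "))
    if ("stage" %in% names(df) && length(unique(df$stage)) > 1L)
      stop_input("one file per round: stage column is not constant")
    if ("stage" %in% names(df) && nrow(df)) stage <- df$stage[1L]
    df <- df[!is.na(df$rating) & nzchar(trimws(df$rating)), , drop = FALSE]
    long <- data.frame(item = df$item, rater = df$rater,
                       rating = parse_rating(df$rating, df$item, df$rater, scale),
                       stringsAsFactors = FALSE)
  } else {
    if (!"rater" %in% names(df))
      stop_input("wide-form ratings need a rater column")
    item_cols <- setdiff(names(df), c("rater", "stage"))
    if (!length(item_cols)) stop_input("wide-form ratings have no item columns")
    pieces <- lapply(item_cols, function(it) {
      keep <- !is.na(df[[it]]) & nzchar(trimws(df[[it]]))
      if (!any(keep)) return(NULL)
      data.frame(item = it, rater = df$rater[keep],
                 rating = parse_rating(df[[it]][keep], it, df$rater[keep], scale),
                 stringsAsFactors = FALSE)
    })
    long <- do.call(rbind, pieces)
    # preserve the file's column order, not rbind order side effects
    long <- long[order(match(long$item, item_cols)), , drop = FALSE]
  }
  dup <- duplicated(long[c("item", "rater")])
  if (any(dup))
    stop_input("duplicate rating for item %s by rater %s",
               long$item[dup][1L], long$rater[dup][1L])
  item_order <- unique(long$item)
  items <- lapply(item_order, function(it) {
    item_ratings(it, long$rating[long$item == it], scale = scale, stage = stage)
  })
  panel_round(items, scale = scale, stage = stage)
}

parse_rating <- function(x, item, rater, scale) {
  v <- suppressWarnings(as.numeric(trimws(x)))
  bad <- is.na(v) | v != round(v) | v < scale$minimum | v > scale$maximum
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_input("invalid rating '%s' for item %s, rater %s (scale %d..%d)",
               trimws(x[i]), rep_len(item, length(x))[i],
               rep_len(rater, length(x))[i], scale$minimum, scale$maximum)
  }
  as.integer(v)
}

#' Write a panel round as a long-form CSV
#'
#' Inverse of [read_ratings()]: raters are labelled `r1`, `r2`, ... within
#' each item (the engine is rater-exchangeable, so synthetic identities
#' carry no information). Reading the file back reproduces the identical
#' rating multiset per item.
#'
#' @param round a [panel_round()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(round, path) {
  stopifnot(inherits(round, "panel_round"))
  rows <- lapply(round$items, function(it) {
    if (!it$n_responses) return(NULL)
    data.frame(item = it$item_id, rater = paste0("r", seq_len(it$n_responses)),
               rating = it$ratings, stage = it$stage, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows) %||%
    data.frame(item = character(), rater = character(),
               rating = integer(), stage = character())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate an item's rating distribution
#'
#' Counts of raters per scale point, zeros included, in ascending scale
#' order -- the numeric content of the rating-distribution panels used to
#' display a round (tall, thin distributions mean agreement; flat ones,
#' the lack of it).
#'
#' @param item an [item_ratings()].
#' @return a data frame with columns `score` and `count`; the counts sum
#'   to the item's `n_responses`.
#' @export
#' @examples
#' distribution_summary(item_ratings("6a", rep(8, 17)))
distribution_summary <- function(item) {
  stopifnot(inherits(item, "item_ratings"))
  pts <- scale_points(item$scale)
  counts <- vapply(pts, function(s) sum(item$ratings == s), 0L)
  data.frame(score = pts, count = counts)
}

#' Write a round's appropriateness results as CSV
#'
#' Serializes the output of [analyze_round()] (or
#' [analyze_summaries()]) in the layout of a published consensus report:
#' one row per item with the median, 30th/70th centiles, IPR, IPR central
#' point, asymmetry index, IPRAS, disagreement index and both verdicts.
#' Display rounding follows `config` (medians to 1 dp, disagreement index
#' to `display_decimals_di`); `full_precision = TRUE` appends unrounded
#' companion columns.
#'
#' @param results data frame from [analyze_round()] / [analyze_summaries()].
#' @param path output CSV path.
#' @param config an [engine_config()] (controls display rounding).
#' @param full_precision append `*_full` columns with unrounded values.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = engine_config(),
                          full_precision = FALSE) {
  stopifnot(is.data.frame(results))
  cols <- c("item", "stage", "median", "p30", "p70", "ipr", "iprcp", "ai",
            "ipras", "disagreement_index", "appropriateness", "disagreement")
  if (!nrow(results)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols))
    stop_input("results are missing columns: %s", paste(missing_cols, collapse = ", "))
  out <- results[cols]
  out$median <- round_half_away(out$median, 1)
  for (cc in c("ipr", "iprcp", "ai", "ipras"))
    out[[cc]] <- round_half_away(out[[cc]], 2)
  out$disagreement_index <- round_half_away(out$disagreement_index,
                                            config$display_decimals_di)
  extra <- intersect(c("n", "unstable"), names(results))
  out <- cbind(out, results[extra])
  if (full_precision) {
    for (cc in c("median", "ipr", "iprcp", "ai", "ipras", "disagreement_index"))
      out[[paste0(cc, "_full")]] <- results[[cc]]
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
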