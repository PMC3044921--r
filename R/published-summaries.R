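#' Published panel summaries from the moderator-criteria consensus study
#'
#' The per-item summary statistics published by the two-round expert
#' consensus on criteria for appraising moderator analyses in randomised
#' trials: median, 30th and 70th centile, appropriateness category and
#' disagreement index for the 13 first-round items (rated by a panel of
#' 17) and the 4 second-round items (rated by 15 of the same panel). The
#' raw ratings were never published, so this table is both the reference
#' for the summary-only analysis mode and the input for the inverse
#' multiset search.
#'
#' Two second-round rows are known to be internally inconsistent with the
#' published chain (item 3: printed DI 0.29 vs recomputed 0.22; item 4:
#' centiles (2,2) imply DI 0 yet print 0.96) and one first-round row
#' (item 3a, median 5.5) prints a category contradicting the median rule;
#' [analyze_summaries()] flags all three, the first two on the numeric
#' chain and the last on the category.
#'
#' @param stage `"1"`, `"2"`, or `"all"` (default).
#' @return a data frame with columns `item`, `stage`, `median`, `p30`,
#'   `p70`, `appropriateness`, `disagreement_index` (values as printed),
#'   with attribute `panel_sizes` = `c("1" = 17, "2" = 15)`.
#' @export
#' @examples
#' head(panel_summaries())
panel_summaries <- function(stage = c("all", "1", "2")) {
  stage <- match.arg(stage)
  path <- system.file("extdata", "panel_summaries.csv", package = "randucla",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(item = "character", stage = "character"))
  if (stage != "all") df <- df[df$stage == stage, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "panel_sizes") <- c("1" = 17L, "2" = 15L)
  df
}
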