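# Shared fixtures and independent oracles for the suite.

# Brute-force percentile oracle: sorts and interpolates from first
# principles, independent of the package's stats::quantile-backed path.
oracle_percentile <- function(ratings, p, method = "linear_interpolation") {
  x <- sort(as.numeric(ratings))
  n <- length(x)
  if (method == "linear_interpolation") {
    h <- (n - 1) * p + 1
    j <- floor(h)
    g <- h - j
    if (j >= n) x[n] else x[j] + g * (x[j + 1] - x[j])
  } else {
    if (p <= 0) x[1] else x[ceiling(n * p)]
  }
}

# All multisets of size n over scores 0..smax, one per column, via the
# standard bijection with combinations of distinct values.
all_multisets <- function(n, smax = 8L) {
  combn(seq_len(smax + n) - 1L, n) - (seq_len(n) - 1L)
}

# The bundled published summaries split into chain-consistent rows and
# the two rows whose printed DI contradicts the printed centiles.
consistent_summaries <- function() {
  s <- panel_summaries()
  s[!(s$stage == "2" & s$item %in% c("3", "4")), , drop = FALSE]
}

write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A complete appraisal from a named response vector, attaching valid
# exception codes where the response requires one.
make_appraisal <- function(study_id, responses, codes = NULL) {
  answers <- lapply(criterion_ids, function(id) {
    code <- if (!is.null(codes) && !is.null(codes[[id]])) codes[[id]]
            else if (responses[[id]] == "not_applicable") "time_invariant_factor"
            else NA_character_
    criterion_answer(id, responses[[id]], code)
  })
  study_appraisal(study_id, answers)
}

grade_of <- function(responses, ...) {
  grade_study(make_appraisal("s", responses, ...))$grade
}
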