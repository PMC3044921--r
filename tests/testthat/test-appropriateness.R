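test_that("percentile follows both small-sample conventions", {
  expect_equal(rating_percentile(rep(4, 5), 0.3), 4)
  expect_equal(rating_percentile(0:8, 0.5), 4)
  # h = 9*0.3 + 1 = 3.7: x(3) + 0.7*(x(4) - x(3)) = 2.7
  expect_equal(rating_percentile(c(0:8, 8), 0.3), 2.7)
  # nearest rank: x(ceiling(10*0.3)) = x(3) = 2
  expect_equal(rating_percentile(c(0:8, 8), 0.3, "nearest_rank"), 2)
  expect_equal(rating_percentile(c(5, 1, 3), 0, "nearest_rank"), 1)
  expect_error(rating_percentile(numeric(0), 0.3), "no ratings")
  expect_error(rating_percentile(1:3, 1.2), "p must be")
})

test_that("median handles odd and even panels", {
  expect_equal(rating_median(c(8, 8, 8)), 8)
  expect_equal(rating_median(c(6, 7)), 6.5)
  expect_equal(rating_median(c(0, 0, 8, 8)), 4)
  expect_error(rating_median(numeric(0)), "no ratings")
})

test_that("summary-mode chain reproduces published disagreement indices", {
  cases <- list(  # item, median, p30, p70, di printed at 2 dp
    list("1a", 6.0, 6, 7, 0.16),
    list("2a", 4.0, 3, 5, 0.85),
    list("6a", 8.0, 8, 8, 0.00))
  for (cs in cases) {
    s <- statistics_from_percentiles(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(round_half_away(s$disagreement_index, 2), cs[[5]],
                 info = cs[[1]])
    expect_true(is.na(s$n))
    expect_true(s$summary_only)
  }
  # intermediate quantities of the chain for the asymmetric case
  s <- statistics_from_percentiles("1a", 6.0, 6, 7)
  expect_equal(s$ipr, 1)
  expect_equal(s$iprcp, 6.5)
  expect_equal(s$ai, 2.5)
  expect_equal(s$ipras, 6.10)
  expect_error(statistics_from_percentiles("x", 4, 5, 3), "exceeds")
  expect_error(statistics_from_percentiles("x", 4, 3, 9), "outside scale")
})

test_that("ipras equals its floor exactly when ratings are symmetric about the midpoint", {
  sym <- statistics_from_percentiles("s", 4, 3, 5)
  expect_equal(sym$ipras, 2.35)
  asym <- statistics_from_percentiles("a", 6, 5, 7)
  expect_gt(asym$ipras, 2.35)
})

test_that("appropriateness classification follows the median thresholds", {
  expect_equal(classify_appropriateness(8.0), "appropriate")
  expect_equal(classify_appropriateness(6.0), "appropriate")
  expect_equal(classify_appropriateness(5.9), "uncertain")
  expect_equal(classify_appropriateness(4.0), "uncertain")
  expect_equal(classify_appropriateness(3.0), "uncertain")
  expect_equal(classify_appropriateness(2.9), "inappropriate")
  expect_equal(classify_appropriateness(0.0), "inappropriate")
  expect_error(classify_appropriateness(9), "outside scale")
})

test_that("disagreement is declared at index 1.0 and above only", {
  expect_true(classify_disagreement(1.09))
  expect_true(classify_disagreement(1.0))   # "less than 1.0" is no disagreement
  expect_false(classify_disagreement(0.97))
  expect_false(classify_disagreement(0))
  expect_error(classify_disagreement(-0.1), ">= 0")
})

test_that("analyze_item runs the full chain from raw ratings", {
  const <- analyze_item(item_ratings("c", rep(8, 10)))
  expect_equal(const$median, 8)
  expect_equal(const$ipr, 0)
  expect_equal(const$disagreement_index, 0)
  expect_equal(const$appropriateness, "appropriate")
  expect_false(const$disagreement)

  # split panel, closed form: p30 0, p70 8, ipr 8, iprcp 4 = midpoint,
  # ai 0, ipras 2.35, di = 8/2.35 = 3.404...
  split <- analyze_item(item_ratings("s", c(rep(0, 8), rep(8, 8))))
  expect_equal(split$p30, 0)
  expect_equal(split$p70, 8)
  expect_equal(split$ipr, 8)
  expect_equal(split$ai, 0)
  expect_equal(split$ipras, 2.35)
  expect_equal(split$disagreement_index, 8 / 2.35, tolerance = 1e-12)
  expect_true(split$disagreement)

  expect_error(analyze_item(item_ratings("e", integer(0))), "no responses")
})

test_that("analyze_item agrees with the summary-mode chain fed its own percentiles", {
  set.seed(11)
  for (i in 1:25) {
    r <- sample(0:8, sample(3:20, 1), replace = TRUE)
    full <- analyze_item(item_ratings("x", r))
    summ <- statistics_from_percentiles("x", full$median, full$p30, full$p70)
    expect_equal(summ$ipr, full$ipr)
    expect_equal(summ$ipras, full$ipras)
    expect_equal(summ$disagreement_index, full$disagreement_index)
  }
})

test_that("statistics are permutation-invariant and reflection-symmetric", {
  set.seed(5)
  for (i in 1:20) {
    r <- sample(0:8, sample(4:18, 1), replace = TRUE)
    a <- analyze_item(item_ratings("x", r))
    b <- analyze_item(item_ratings("x", sample(r)))
    expect_equal(a[c("median", "p30", "p70", "disagreement_index")],
                 b[c("median", "p30", "p70", "disagreement_index")])
    # reflect every rating about the scale: r -> 8 - r
    refl <- analyze_item(item_ratings("x", 8 - r))
    expect_equal(refl$ipr, a$ipr, tolerance = 1e-12)
    expect_equal(refl$ai, a$ai, tolerance = 1e-12)
    expect_equal(refl$ipras, a$ipras, tolerance = 1e-12)
    expect_equal(refl$disagreement_index, a$disagreement_index,
                 tolerance = 1e-12)
    expect_equal(refl$median, 8 - a$median, tolerance = 1e-12)
  }
})

test_that("disagreement index rises with spread and falls with asymmetry", {
  scale <- rating_scale()
  cfg <- engine_config()
  # ipr increasing at fixed central point
  di <- function(p30, p70)
    statistics_from_percentiles("m", (p30 + p70) / 2, p30, p70)$disagreement_index
  expect_true(di(3, 5) < di(2, 6) && di(2, 6) < di(1, 7) && di(1, 7) < di(0, 8))
  # asymmetry increasing at fixed ipr
  expect_true(di(3, 5) > di(4, 6) && di(4, 6) > di(5, 7) && di(5, 7) > di(6, 8))
})

test_that("percentile matches an independent brute-force oracle on sampled multisets", {
  set.seed(99)
  for (i in 1:400) {
    r <- sample(0:8, sample(2:30, 1), replace = TRUE)
    p <- sample(c(0.3, 0.7, runif(1)), 1)
    for (m in c("linear_interpolation", "nearest_rank"))
      expect_equal(rating_percentile(r, p, m), oracle_percentile(r, p, m),
                   info = sprintf("n=%d p=%.3f %s", length(r), p, m))
  }
})

test_that("round analysis preserves item order, flags small panels, and handles 13-item rounds", {
  set.seed(3)
  items <- lapply(c("1a", "1b", "2a"), function(id)
    item_ratings(id, sample(0:8, 17, replace = TRUE)))
  res <- analyze_round(panel_round(items))
  expect_equal(res$item, c("1a", "1b", "2a"))
  expect_false(any(res$unstable))

  small <- analyze_round(panel_round(list(item_ratings("tiny", c(4, 5, 6)))))
  expect_true(small$unstable)

  expect_equal(nrow(analyze_round(panel_round(list()))), 0L)
  items13 <- lapply(sprintf("i%d", 1:13), function(id)
    item_ratings(id, sample(0:8, 17, replace = TRUE)))
  expect_equal(nrow(analyze_round(panel_round(items13))), 13L)
})

test_that("summary checker flags DI mismatches and continues past impossible rows", {
  df <- data.frame(item = c("ok", "off", "bad"),
                   median = c(4, 4, 4), p30 = c(3, 3, 5), p70 = c(5, 5, 3),
                   disagreement_index = c(0.85, 0.50, 0.10))
  out <- analyze_summaries(df)
  expect_equal(out$flagged, c(FALSE, TRUE, TRUE))
  expect_false(is.na(out$row_error[3]))
  expect_equal(nrow(out), 3L)

  # classic-RAND demotion mode: disagreement overrides the category
  dem <- statistics_from_percentiles("d", 6.5, 0, 6,
                                     config = engine_config(demote_disagreement = TRUE))
  expect_true(dem$disagreement)
  expect_equal(dem$appropriateness, "uncertain")
})
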