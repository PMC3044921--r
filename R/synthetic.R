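#' Panel response profile
#'
#' A stochastic description of how a panel rates one item, used by
#' [generate_panel()]. Built-in shapes mirror the response patterns seen
#' in real consensus rounds:
#'
#' * `consensus_high` -- unanimous endorsement: all mass on the scale
#'   maximum (a tall, thin distribution at the top of the scale).
#' * `consensus_low` -- unanimous rejection: all mass on the minimum.
#' * `indifferent` -- ratings spread uniformly over the middle band
#'   (scores 3..5 on the default scale), producing an uncertain verdict.
#' * `polarized` -- two camps at the extremes: mass 1/2 on the minimum
#'   and 1/2 on the maximum.
#' * `custom` -- any `score_probabilities` the caller supplies, with a
#'   `designed_category` naming the engine verdict the profile is meant
#'   to produce (used by [recovery_experiment()]).
#'
#' @param name profile shape (see above).
#' @param score_probabilities named numeric vector, names = scale scores,
#'   summing to 1; required for `custom`, derived otherwise.
#' @param response_rate probability a rater responds for the item
#'   (0 < rate <= 1; default 1).
#' @param n_raters panel size (default 17, a typical first-round panel).
#' @param scale a [rating_scale()].
#' @param designed_category engine verdict the profile is designed to
#'   elicit: `"appropriate"`, `"inappropriate"`, `"uncertain"` or
#'   `"disagreement"`; derived from `name` for built-in shapes.
#' @return an object of class `panel_profile`.
#' @export
#' @examples
#' panel_profile("polarized")
#' panel_profile("custom", c(`6` = 0.5, `7` = 0.3, `8` = 0.2),
#'               designed_category = "appropriate")
panel_profile <- function(name = c("consensus_high", "consensus_low",
                                   "indifferent", "polarized", "custom"),
                          score_probabilities = NULL, response_rate = 1,
                          n_raters = 17L, scale = rating_scale(),
                          designed_category = NULL) {
  name <- match.arg(name)
  assert_rating_scale(scale)
  if (!(response_rate > 0 && response_rate <= 1))
    stop_input("response_rate must be in (0, 1]")
  n_raters <- as.integer(n_raters)
  if (n_raters < 1L) stop_input("n_raters must be >= 1")
  pts <- scale_points(scale)
  mid_band <- pts[pts >= scale$inappropriate_threshold &
                  pts < scale$appropriate_threshold]
  if (is.null(score_probabilities)) {
    score_probabilities <- switch(
      name,
      consensus_high = setNames(1, scale$maximum),
      consensus_low = setNames(1, scale$minimum),
      indifferent = setNames(rep(1 / length(mid_band), length(mid_band)), mid_band),
      polarized = setNames(c(0.5, 0.5), c(scale$minimum, scale$maximum)),
      custom = stop_input("custom profile requires score_probabilities"))
  }
  probs <- as.numeric(score_probabilities)
  scores <- as.integer(names(score_probabilities))
  if (anyNA(scores) || any(!scores %in% pts))
    stop_input("score_probabilities must be named by scale scores %d..%d",
               scale$minimum, scale$maximum)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop_input("score probabilities must be non-negative and sum to 1")
  if (name == "polarized") {
    ext <- probs[scores %in% c(scale$minimum, scale$maximum)]
    if (sum(ext) < 0.8 || (length(ext) == 2L && abs(ext[1] - ext[2]) > 1e-8))
      stop_input("polarized profile needs >= 0.8 mass on the two extremes, split evenly")
  }
  designed_category <- designed_category %||% switch(
    name, consensus_high = "appropriate", consensus_low = "inappropriate",
    indifferent = "uncertain", polarized = "disagreement",
    custom = stop_input("custom profile requires designed_category"))
  designed_category <- match.arg(
    designed_category, c("appropriate", "inappropriate", "uncertain", "disagreement"))
  structure(list(name = name,
                 score_probabilities = setNames(probs, scores),
                 response_rate = response_rate, n_raters = n_raters,
                 scale = scale, designed_category = designed_category),
            class = "panel_profile")
}

#' @export
print.panel_profile <- function(x, ...) {
  cat(sprintf("<panel_profile> %s: %d raters, response rate %.2f, P(score): %s\n",
              x$name, x$n_raters, x$response_rate,
              paste(sprintf("%s=%.2f", names(x$score_probabilities),
                            x$score_probabilities), collapse = " ")))
  invisible(x)
}

#' Generate a synthetic panel round
#'
#' For each item, draws `n_raters` independent scores from the profile's
#' score distribution, then drops each response independently with
#' probability `1 - response_rate` (nonresponse is missing-at-random and
#' responses are never imputed). Entirely driven by the explicit `seed`:
#' the same seed and profiles regenerate the identical round.
#'
#' @param items item count, or character vector of item ids.
#' @param profiles one [panel_profile()] recycled over items, or a list
#'   of profiles, one per item.
#' @param seed integer seed; all randomness derives from it.
#' @param stage round label.
#' @return an object of class `generated_round`: list with `round` (a
#'   [panel_round()]), `seed`, and `profiles_used` (named by item).
#' @export
#' @examples
#' g <- generate_panel(3, panel_profile("consensus_high", n_raters = 10), seed = 1)
#' analyze_round(g$round)
generate_panel <- function(items, profiles, seed, stage = "1") {
  if (inherits(profiles, "panel_profile")) profiles <- list(profiles)
  if (!all(vapply(profiles, inherits, TRUE, "panel_profile")))
    stop_input("profiles must be panel_profile objects")
  ids <- if (is.character(items)) items else paste0("item", seq_len(items))
  if (length(profiles) == 1L) profiles <- rep(profiles, length(ids))
  if (length(profiles) != length(ids))
    stop_input("need one profile per item (%d items, %d profiles)",
               length(ids), length(profiles))
  names(profiles) <- ids
  scale <- profiles[[1L]]$scale
  for (pf in profiles)
    if (pf$n_raters * pf$response_rate <= 0)
      stop_input("profile with zero expected responses")
  round <- with_seed(seed, {
    its <- lapply(ids, function(id) {
      pf <- profiles[[id]]
      drawn <- draw_scores(pf)
      kept <- drawn[rbinom(pf$n_raters, 1L, pf$response_rate) == 1L]
      item_ratings(id, kept, scale = scale, stage = stage,
                   n_raters_invited = pf$n_raters)
    })
    panel_round(its, scale = scale, stage = stage)
  })
  structure(list(round = round, seed = as.integer(seed),
                 profiles_used = profiles),
            class = "generated_round")
}

#' @export
print.generated_round <- function(x, ...) {
  cat(sprintf("<generated_round> seed %d: ", x$seed))
  print(x$round)
  invisible(x)
}

# index-based sampling: sample(x, ...) would misread a single score as 1:x
draw_scores <- function(pf) {
  scores <- as.integer(names(pf$score_probabilities))
  scores[sample.int(length(scores), pf$n_raters, replace = TRUE,
                    prob = pf$score_probabilities)]
}

#' Recover a rating multiset from printed summary statistics
#'
#' Inverse problem for published consensus tables: find `n` in-scale
#' integer ratings whose computed median and centile pair -- rounded to
#' the table's printed precision (median 1 dp, centiles 0 dp by default)
#' -- equal the printed targets, and whose disagreement index (computed
#' from the exact, unrounded centiles) agrees at display precision with
#' the index implied by the printed centiles, so a recovered multiset
#' reproduces the published row end to end. The search walks
#' non-decreasing score vectors in lexicographic order with interval
#' pruning at the order statistics that determine each target, so the
#' first match found is the lexicographically smallest and is stable
#' across runs and platforms; exhausting the space proves infeasibility
#' under the configured quantile method (e.g. any half-integer median is
#' infeasible at odd `n`, where the median is a single order statistic).
#'
#' @param n multiset size (>= 1; intended for the small-panel range,
#'   n <= 20 or so).
#' @param target_median printed median (1 dp).
#' @param target_p30,target_p70 printed centiles (integers as published).
#' @param scale a [rating_scale()].
#' @param config an [engine_config()] (supplies the centile pair and
#'   quantile method).
#' @param rounding list with `median` and `centiles` decimal places used
#'   to match the printed precision.
#' @return an integer vector of `n` sorted ratings, or `NULL` when no
#'   multiset can reproduce the targets.
#' @export
#' @examples
#' find_ratings_matching(5, 8, 8, 8)        # forced: c(8,8,8,8,8)
#' find_ratings_matching(17, 6.5, 6, 8)     # NULL: odd n, half-integer median
find_ratings_matching <- function(n, target_median, target_p30, target_p70,
                                  scale = rating_scale(),
                                  config = engine_config(),
                                  rounding = list(median = 1L, centiles = 0L)) {
  assert_rating_scale(scale)
  n <- as.integer(n)
  if (n <= 0L) stop_input("n must be positive")
  targets <- c(target_p30, target_median, target_p70)
  if (any(targets < scale$minimum | targets > scale$maximum))
    stop_input("targets outside scale %d..%d", scale$minimum, scale$maximum)
  if (!(target_p30 <= target_median && target_median <= target_p70))
    return(NULL)

  stats <- list(
    quantile_positions(n, config$lower_p, config$quantile_method,
                       target_p30, rounding$centiles),
    median_positions(n, target_median, rounding$median),
    quantile_positions(n, config$upper_p, config$quantile_method,
                       target_p70, rounding$centiles))
  last_checked <- max(vapply(stats, `[[`, 0L, "imax"))

  # per-depth bounds: x is non-decreasing, every statistic's value lies
  # between x[imin] and x[imax], and must round into [t - h, t + h)
  lo <- rep(scale$minimum, n)
  hi <- rep(scale$maximum, n)
  for (s in stats) {
    ub <- floor(s$vmax - 1e-9)          # x[imin] <= value < vmax
    lb <- ceiling(s$vmin)               # x[imax] >= value >= vmin
    hi[seq_len(s$imin)] <- pmin(hi[seq_len(s$imin)], ub)
    if (s$imax <= n) lo[s$imax:n] <- pmax(lo[s$imax:n], lb)
  }
  if (any(lo > hi)) return(NULL)

  # the disagreement index the printed centiles imply; the recovered
  # multiset's exact centiles must reproduce it at display precision
  target_di <- statistics_from_percentiles(
    "target", target_median, target_p30, target_p70, scale, config
  )$disagreement_index
  di_matches <- function(x) {
    s <- stats
    p30 <- stat_value(s[[1L]], x)
    p70 <- stat_value(s[[3L]], x)
    ai <- abs(scale$midpoint - (p30 + p70) / 2)
    di <- (p70 - p30) / (config$ipr_r + ai * config$cfa)
    round_half_away(di, config$display_decimals_di) ==
      round_half_away(target_di, config$display_decimals_di)
  }

  x <- integer(n)
  search <- function(depth, last) {
    from <- max(last, lo[depth])
    if (from > hi[depth]) return(NULL)
    for (v in from:hi[depth]) {
      x[depth] <<- v
      ok <- TRUE
      for (s in stats) {
        if (s$imax == depth && !stat_matches(s, x)) { ok <- FALSE; break }
      }
      if (!ok) next
      if (depth == last_checked) {
        if (di_matches(x)) return(c(x[seq_len(depth)], rep(v, n - depth)))
        next
      }
      hit <- search(depth + 1L, v)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  out <- search(1L, scale$minimum)
  if (is.null(out)) NULL else as.integer(out)
}

quantile_positions <- function(n, p, method, target, digits) {
  if (method == "linear_interpolation") {
    h <- (n - 1) * p + 1
    j <- floor(h); g <- h - j
    idx <- if (g > 1e-12 && j < n) c(j, j + 1L) else j
    weight <- g
  } else {
    idx <- max(1L, ceiling(n * p))
    weight <- 0
  }
  half <- 0.5 * 10^(-digits)
  list(idx = as.integer(idx), imin = as.integer(min(idx)),
       imax = as.integer(max(idx)), weight = weight, target = target,
       digits = digits, vmin = target - half, vmax = target + half,
       kind = "quantile")
}

median_positions <- function(n, target, digits) {
  idx <- if (n %% 2L == 1L) (n + 1L) %/% 2L else c(n %/% 2L, n %/% 2L + 1L)
  half <- 0.5 * 10^(-digits)
  list(idx = as.integer(idx), imin = as.integer(min(idx)),
       imax = as.integer(max(idx)), weight = NA_real_, target = target,
       digits = digits, vmin = target - half, vmax = target + half,
       kind = "median")
}

stat_value <- function(s, x) {
  if (s$kind == "median") mean(x[s$idx])
  else if (length(s$idx) == 2L)
    x[s$idx[1L]] + s$weight * (x[s$idx[2L]] - x[s$idx[1L]])
  else x[s$idx]
}

stat_matches <- function(s, x) {
  round_half_away(stat_value(s, x), s$digits) ==
    round_half_away(s$target, s$digits)
}

#' Classification recovery over synthetic panels
#'
#' Monte-Carlo check that the engine recovers the verdict each profile is
#' designed to elicit. For every profile, `replicates` single-item panels
#' are generated and analyzed, and the fraction whose classification
#' matches the profile's `designed_category` is reported (`"disagreement"`
#' matches on the disagreement flag, the other categories on the
#' appropriateness verdict with no disagreement). Deterministic given
#' `seed`.
#'
#' @param profiles list of [panel_profile()]s (optionally named).
#' @param replicates number of panels per profile (>= 1).
#' @param seed integer seed.
#' @param config an [engine_config()].
#' @return a data frame with one row per profile: `profile`,
#'   `designed_category`, `n_raters`, `replicates`, `recovered`
#'   (fraction in `[0, 1]`).
#' @export
#' @examples
#' recovery_experiment(list(panel_profile("consensus_high")), 20, seed = 1)
recovery_experiment <- function(profiles, replicates, seed,
                                config = engine_config()) {
  if (inherits(profiles, "panel_profile")) profiles <- list(profiles)
  stopifnot(replicates >= 1)
  nm <- names(profiles) %||% vapply(profiles, `[[`, "", "name")
  nm[!nzchar(nm)] <- vapply(profiles[!nzchar(nm)], `[[`, "", "name")
  rows <- with_seed(seed, {
    lapply(seq_along(profiles), function(i) {
      pf <- profiles[[i]]
      hits <- 0L
      for (rep in seq_len(replicates)) {
        # draw directly (inside the seeded stream) rather than re-seeding
        drawn <- draw_scores(pf)
        kept <- drawn[rbinom(pf$n_raters, 1L, pf$response_rate) == 1L]
        if (!length(kept)) next
        s <- analyze_item(item_ratings("x", kept, scale = pf$scale),
                          pf$scale, config)
        ok <- if (pf$designed_category == "disagreement") s$disagreement
              else s$appropriateness == pf$designed_category && !s$disagreement
        if (ok) hits <- hits + 1L
      }
      data.frame(profile = nm[i], designed_category = pf$designed_category,
                 n_raters = pf$n_raters, replicates = replicates,
                 recovered = hits / replicates, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
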