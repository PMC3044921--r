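yes5 <- setNames(rep("yes", 5), criterion_ids)

test_that("criterion answers validate responses and exception codes", {
  expect_true(judge_criterion(criterion_answer("c5_interaction_test", "yes")))
  expect_false(judge_criterion(
    criterion_answer("c1_a_priori", "no", "vague_hypothesis")))
  # a recognised exception waives the pre-randomisation requirement
  expect_true(judge_criterion(
    criterion_answer("c3_pre_randomisation", "not_applicable",
                     "time_invariant_factor")))
  expect_true(judge_criterion(
    criterion_answer("c3_pre_randomisation", "not_applicable",
                     "cluster_randomisation_pre_awareness")))
  # "not reported" never satisfies
  expect_false(judge_criterion(criterion_answer("c2_theory_evidence", "unknown")))

  expect_error(criterion_answer("c3_pre_randomisation", "not_applicable"),
               "exception code")
  expect_error(criterion_answer("c4_measurement_quality", "not_applicable",
                                "time_invariant_factor"),
               "no not_applicable")
  expect_error(criterion_answer("c9_bogus", "yes"), "unknown criterion")
  expect_error(criterion_answer("c1_a_priori", "no", "wrong_code"),
               "failure code")
})

test_that("appraisals require exactly one answer per criterion", {
  expect_error(study_appraisal("s", list(criterion_answer("c1_a_priori", "yes"))),
               "exactly one answer")
  four <- lapply(criterion_ids[-5], criterion_answer, response = "yes")
  expect_error(study_appraisal("s", four), "exactly one")
})

test_that("grading applies the confirmatory / exploratory / excluded rules", {
  expect_equal(grade_of(yes5), "confirmatory")

  post_hoc <- yes5
  post_hoc[c("c1_a_priori", "c2_theory_evidence")] <- "no"
  expect_equal(grade_of(post_hoc), "exploratory")

  sep <- yes5
  sep["c5_interaction_test"] <- "no"
  g <- grade_study(make_appraisal(
    "s", sep, codes = list(c5_interaction_test = "subgroups_tested_separately")))
  expect_equal(g$grade, "excluded")
  expect_equal(g$failed_criteria, "c5_interaction_test")

  # weak theory demotes to exploratory but can never exclude
  weak <- yes5
  weak["c2_theory_evidence"] <- "no"
  expect_equal(grade_of(weak), "exploratory")

  # a waived core criterion still counts as satisfied
  sex_mod <- yes5
  sex_mod["c3_pre_randomisation"] <- "not_applicable"
  expect_equal(grade_of(sex_mod), "confirmatory")
})

test_that("all valid answer combinations partition into exactly one grade", {
  responses <- list(
    c1_a_priori = c("yes", "no", "unknown"),
    c2_theory_evidence = c("yes", "no", "unknown"),
    c3_pre_randomisation = c("yes", "no", "unknown", "not_applicable"),
    c4_measurement_quality = c("yes", "no", "unknown"),
    c5_interaction_test = c("yes", "no", "unknown"))
  grid <- expand.grid(responses, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    resp <- unlist(grid[i, ])
    g <- grade_study(make_appraisal("s", resp))
    sat <- resp == "yes" | resp == "not_applicable"
    core_ok <- all(sat[c("c3_pre_randomisation", "c4_measurement_quality",
                         "c5_interaction_test")])
    expected <- if (all(sat)) "confirmatory"
                else if (core_ok) "exploratory"
                else "excluded"
    expect_equal(g$grade, expected)
    # the three definitions are mutually exclusive by construction
    expect_equal(setdiff(criterion_ids, g$failed_criteria),
                 criterion_ids[sat])
  }
})

test_that("improving any single answer never lowers the grade", {
  rank <- c(excluded = 1L, exploratory = 2L, confirmatory = 3L)
  combos <- expand.grid(rep(list(c("no", "yes")), 5), stringsAsFactors = FALSE)
  names(combos) <- criterion_ids
  for (i in seq_len(nrow(combos))) {
    base <- unlist(combos[i, ])
    g0 <- rank[[grade_of(base)]]
    for (id in criterion_ids[base == "no"]) {
      up <- base
      up[id] <- "yes"
      expect_gte(rank[[grade_of(up)]], g0)
    }
  }
})

test_that("review summaries count grades and criterion satisfaction", {
  s0 <- summarize_review(list())
  expect_equal(unname(s0$counts), c(0L, 0L, 0L))

  apps <- c(lapply(1:3, function(i) make_appraisal(paste0("c", i), yes5)),
            lapply(1:2, function(i) {
              r <- yes5
              r["c5_interaction_test"] <- "no"
              make_appraisal(paste0("x", i), r)
            }))
  grades <- lapply(apps, grade_study)
  s <- summarize_review(grades, apps)
  expect_equal(s$counts[["confirmatory"]], 3L)
  expect_equal(s$counts[["exploratory"]], 0L)
  expect_equal(s$counts[["excluded"]], 2L)
  expect_equal(s$criterion_table$satisfied + s$criterion_table$unsatisfied,
               rep(5L, 5))
})

test_that("appraisal CSV round-trips through read_appraisals and grade_review", {
  df <- data.frame(
    study_id = rep(c("trial-A", "trial-B"), each = 5),
    criterion = rep(criterion_ids, 2),
    response = c(rep("yes", 5),
                 c("no", "yes", "not_applicable", "yes", "yes")),
    exception_code = c(rep("", 5),
                       c("vague_hypothesis", "", "time_invariant_factor", "", "")),
    stringsAsFactors = FALSE)
  path <- write_long_csv(df)
  apps <- read_appraisals(path)
  expect_length(apps, 2L)
  rev <- grade_review(apps)
  expect_equal(rev$grades$grade, c("confirmatory", "exploratory"))
  expect_equal(rev$grades$failed_criteria[2], "c1_a_priori")

  bad <- df
  bad$criterion[2] <- "c2_typo"
  expect_error(read_appraisals(write_long_csv(bad)), "unknown criterion")
  expect_length(read_appraisals(write_long_csv(df[0, ])), 0L)
})
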