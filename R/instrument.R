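#' The five moderator-analysis appraisal criteria
#'
#' The consensus instrument for appraising a trial's moderator (subgroup)
#' analysis comprises five criteria:
#'
#' * `c1_a_priori` -- the analysis was stated a priori: an explicit
#'   hypothesis in the protocol naming which subgroups are tested for
#'   which outcome. Not fulfilled when the protocol lists a considerably
#'   large or vague set of hypotheses.
#' * `c2_theory_evidence` -- factor selection was clinically plausible
#'   and theory and/or evidence driven. A judgement the appraiser may
#'   fail for weak backing, but weakness here never excludes a study.
#' * `c3_pre_randomisation` -- moderators were measured before
#'   randomisation. Waived for baseline factors that cannot change over
#'   time (e.g. sex), and for cluster randomisation when measurement
#'   precedes awareness of allocation.
#' * `c4_measurement_quality` -- baseline factors were measured with
#'   adequate, published reliability and validity for the target
#'   population. Not fulfilled when the baseline measure shows inadequate
#'   variability.
#' * `c5_interaction_test` -- an explicit moderator-by-treatment
#'   interaction test is reported (ideally a pooled effect size with 95%
#'   CI). Not fulfilled when subgroups are tested separately or under
#'   excessive multiple testing.
#'
#' All five satisfied makes a study's moderator findings confirmatory;
#' the final three alone make them admissible as exploratory evidence;
#' failing any of the final three excludes the study from meta-analysis
#' of moderators.
#'
#' @format A character vector of the five criterion ids, in order.
#' @export
criterion_ids <- c("c1_a_priori", "c2_theory_evidence", "c3_pre_randomisation",
                   "c4_measurement_quality", "c5_interaction_test")

# per-criterion vocabularies: codes that can waive the requirement when
# the criterion is not applicable, and codes annotating a failure.
na_exception_codes <- list(
  c1_a_priori = character(),
  c2_theory_evidence = character(),
  c3_pre_randomisation = c("time_invariant_factor",
                           "cluster_randomisation_pre_awareness"),
  c4_measurement_quality = character(),
  c5_interaction_test = character())

failure_codes <- list(
  c1_a_priori = c("vague_hypothesis", "hypothesis_list_too_large"),
  c2_theory_evidence = "weak_theory_or_evidence",
  c3_pre_randomisation = character(),
  c4_measurement_quality = "inadequate_variability",
  c5_interaction_test = c("subgroups_tested_separately",
                          "excessive_multiple_testing"))

#' Answer to one appraisal criterion
#'
#' @param criterion_id one of [criterion_ids].
#' @param response `"yes"`, `"no"`, `"not_applicable"` or `"unknown"`.
#'   `not_applicable` is only valid for criteria with recognised
#'   exceptions (pre-randomisation measurement: `time_invariant_factor`,
#'   `cluster_randomisation_pre_awareness`) and requires an
#'   `exception_code`. `unknown` records "not reported" and never
#'   satisfies a criterion.
#' @param exception_code required for `not_applicable`; optional failure
#'   annotation for `no` (e.g. `vague_hypothesis`,
#'   `subgroups_tested_separately`).
#' @param note free-text justification.
#' @return an object of class `criterion_answer`.
#' @export
#' @examples
#' criterion_answer("c3_pre_randomisation", "not_applicable",
#'                  "time_invariant_factor", note = "moderator is sex")
criterion_answer <- function(criterion_id,
                             response = c("yes", "no", "not_applicable", "unknown"),
                             exception_code = NA_character_, note = "") {
  criterion_id <- as.character(criterion_id)
  if (!criterion_id %in% criterion_ids)
    stop_input("unknown criterion id '%s' (valid: %s)", criterion_id,
               paste(criterion_ids, collapse = ", "))
  response <- match.arg(response)
  code <- as.character(exception_code)
  if (response == "not_applicable") {
    valid <- na_exception_codes[[criterion_id]]
    if (!length(valid))
      stop_input("criterion %s admits no not_applicable exception", criterion_id)
    if (is.na(code) || !code %in% valid)
      stop_input("criterion %s: not_applicable requires an exception code in {%s}",
                 criterion_id, paste(valid, collapse = ", "))
  } else if (response == "no" && !is.na(code) &&
             !code %in% failure_codes[[criterion_id]]) {
    stop_input("criterion %s: unknown failure code '%s'", criterion_id, code)
  }
  structure(list(criterion_id = criterion_id, response = response,
                 exception_code = code, note = as.character(note)),
            class = "criterion_answer")
}

#' Judge whether one criterion is satisfied
#'
#' `yes` satisfies; `no` and `unknown` do not; `not_applicable` with a
#' valid exception code satisfies -- the recognised exception waives the
#' requirement (e.g. a time-invariant baseline factor need not be
#' measured before randomisation).
#'
#' @param answer a [criterion_answer()].
#' @return logical: `TRUE` when the criterion is satisfied.
#' @export
judge_criterion <- function(answer) {
  if (!inherits(answer, "criterion_answer"))
    stop_input("expected a criterion_answer")
  switch(answer$response,
         yes = TRUE,
         not_applicable = TRUE,  # validity of the code enforced at construction
         no = FALSE,
         unknown = FALSE)
}

#' A study's complete appraisal
#'
#' @param study_id study label.
#' @param answers list of five [criterion_answer()]s, exactly one per
#'   criterion.
#' @param appraiser appraiser label.
#' @param date appraisal date.
#' @return an object of class `study_appraisal`.
#' @export
study_appraisal <- function(study_id, answers, appraiser = NA_character_,
                            date = Sys.Date()) {
  if (!is.list(answers) ||
      !all(vapply(answers, inherits, TRUE, "criterion_answer")))
    stop_input("answers must be a list of criterion_answer objects")
  ids <- vapply(answers, `[[`, "", "criterion_id")
  if (!setequal(ids, criterion_ids) || length(ids) != length(criterion_ids))
    stop_input("study %s: need exactly one answer per criterion; got {%s}",
               study_id, paste(ids, collapse = ", "))
  answers <- answers[order(match(ids, criterion_ids))]
  names(answers) <- criterion_ids
  structure(list(study_id = as.character(study_id), answers = answers,
                 appraiser = appraiser, date = date),
            class = "study_appraisal")
}

#' Grade a study's moderator evidence
#'
#' Applies the consensus decision rule. With satisfaction judged per
#' criterion by [judge_criterion()]:
#'
#' * all five satisfied: **confirmatory** -- the moderator findings test
#'   their hypothesis;
#' * the final three (pre-randomisation measurement, measurement quality,
#'   interaction test) satisfied but the a-priori and/or theory criterion
#'   failed: **exploratory** -- admissible as hypothesis-generating
#'   evidence;
#' * any of the final three failed: **excluded** from meta-analysis of
#'   moderators.
#'
#' @param appraisal a [study_appraisal()].
#' @return an object of class `evidence_grade`: list with `study_id`,
#'   `grade` (`"confirmatory"`, `"exploratory"` or `"excluded"`),
#'   `failed_criteria` (ids of every unsatisfied criterion) and
#'   `rationale` (generated text citing responses and exception codes).
#' @export
#' @examples
#' yes_all <- lapply(criterion_ids, criterion_answer, response = "yes")
#' grade_study(study_appraisal("trial-1", yes_all))$grade  # confirmatory
grade_study <- function(appraisal) {
  if (!inherits(appraisal, "study_appraisal"))
    stop_input("expected a study_appraisal")
  satisfied <- vapply(appraisal$answers, judge_criterion, TRUE)
  core <- c("c3_pre_randomisation", "c4_measurement_quality",
            "c5_interaction_test")
  grade <- if (all(satisfied)) "confirmatory"
           else if (all(satisfied[core])) "exploratory"
           else "excluded"
  failed <- criterion_ids[!satisfied]
  bits <- vapply(criterion_ids, function(id) {
    a <- appraisal$answers[[id]]
    tag <- if (!is.na(a$exception_code)) sprintf(" [%s]", a$exception_code) else ""
    sprintf("%s: %s%s", id, a$response, tag)
  }, "")
  rationale <- sprintf(
    "%s: %s. %s", appraisal$study_id, grade, paste(bits, collapse = "; "))
  if (grade == "exploratory")
    rationale <- paste(rationale,
                       "A-priori/theory criteria unmet: findings are hypothesis-generating only.")
  if (grade == "excluded")
    rationale <- paste(rationale,
                       sprintf("Core criteria unmet (%s): ineligible for meta-analysis of moderators.",
                               paste(intersect(failed, core), collapse = ", ")))
  structure(list(study_id = appraisal$study_id, grade = grade,
                 failed_criteria = failed, rationale = rationale),
            class = "evidence_grade")
}

#' @export
print.evidence_grade <- function(x, ...) {
  cat(sprintf("<evidence_grade> %s: %s%s\n", x$study_id, x$grade,
              if (length(x$failed_criteria))
                sprintf(" (failed: %s)", paste(x$failed_criteria, collapse = ", "))
              else ""))
  invisible(x)
}

#' Summarize a set of evidence grades
#'
#' @param grades list of [grade_study()] results.
#' @param appraisals optional list of the corresponding
#'   [study_appraisal()]s; when given, a per-criterion satisfaction
#'   frequency table is included.
#' @return a list with `n_studies`, `counts` (named vector over
#'   confirmatory / exploratory / excluded) and `criterion_table` (data
#'   frame of satisfied / unsatisfied counts per criterion, or `NULL`).
#' @export
summarize_review <- function(grades, appraisals = NULL) {
  if (!all(vapply(grades, inherits, TRUE, "evidence_grade")))
    stop_input("grades must be evidence_grade objects")
  levels <- c("confirmatory", "exploratory", "excluded")
  got <- vapply(grades, `[[`, "", "grade")
  counts <- vapply(levels, function(g) sum(got == g), 0L)
  criterion_table <- NULL
  if (!is.null(appraisals)) {
    sat <- vapply(appraisals,
                  function(a) vapply(a$answers, judge_criterion, TRUE),
                  logical(length(criterion_ids)))
    sat <- matrix(sat, nrow = length(criterion_ids),
                  dimnames = list(criterion_ids, NULL))
    criterion_table <- data.frame(
      criterion = criterion_ids,
      satisfied = apply(sat, 1, sum),
      unsatisfied = apply(sat, 1, function(v) sum(!v)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(n_studies = length(grades), counts = counts,
                 criterion_table = criterion_table),
            class = "review_summary")
}

#' @export
print.review_summary <- function(x, ...) {
  cat(sprintf("<review_summary> %d studies: %s\n", x$n_studies,
              paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", ")))
  if (!is.null(x$criterion_table)) print(x$criterion_table)
  invisible(x)
}

#' Read study appraisals from CSV
#'
#' Long form, one row per study x criterion: columns `study_id`,
#' `criterion`, `response`, and optionally `exception_code`, `note`,
#' `appraiser`. Every study must answer all five criteria.
#'
#' @param path CSV path.
#' @return a named list of [study_appraisal()]s, in file order.
#' @export
read_appraisals <- function(path) {
  if (!file.exists(path)) stop_input("appraisal file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("study_id", "criterion", "response")
  if (!all(need %in% names(df)))
    stop_input("appraisal CSV needs columns %s", paste(need, collapse = ", "))
  if (!nrow(df)) return(list())
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))
  codes <- if ("exception_code" %in% names(df))
    blank_to_na(df$exception_code) else rep(NA_character_, nrow(df))
  notes <- if ("note" %in% names(df)) df$note else rep("", nrow(df))
  ids <- unique(df$study_id)
  out <- lapply(ids, function(sid) {
    rows <- which(df$study_id == sid)
    answers <- lapply(rows, function(i)
      criterion_answer(df$criterion[i], df$response[i], codes[i], notes[i]))
    appraiser <- if ("appraiser" %in% names(df)) df$appraiser[rows[1L]] else NA_character_
    study_appraisal(sid, answers, appraiser = appraiser)
  })
  names(out) <- ids
  out
}

#' Grade every appraisal and tabulate
#'
#' @param appraisals list of [study_appraisal()]s (e.g. from
#'   [read_appraisals()]).
#' @return a list with `grades` (data frame: `study_id`, `grade`,
#'   `failed_criteria`, `rationale`) and `summary` (a
#'   [summarize_review()] result).
#' @export
grade_review <- function(appraisals) {
  grades <- lapply(appraisals, grade_study)
  df <- data.frame(
    study_id = vapply(grades, `[[`, "", "study_id"),
    grade = vapply(grades, `[[`, "", "grade"),
    failed_criteria = vapply(grades, function(g)
      paste(g$failed_criteria, collapse = ";"), ""),
    rationale = vapply(grades, `[[`, "", "rationale"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(grades = df, summary = summarize_review(grades, appraisals))
}
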