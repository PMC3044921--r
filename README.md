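# randucla

RAND/UCLA appropriateness analysis for expert consensus (Delphi) panels,
and a five-criterion instrument for grading moderator (subgroup) analyses
of randomised controlled trials as confirmatory or exploratory evidence in
systematic reviews.

## Who this is for

Methodologists running or re-analysing consensus panels in which a small
group of experts (typically 15–21 raters) scores items on a bounded integer
scale, by default 0 (completely inappropriate) to 8 (extremely important);
and systematic reviewers who need to decide which trials' moderator
analyses may enter a meta-analysis, and with what evidential status.

## The statistics

For each item with ratings on the 0–8 scale, the package computes:

- the median *M*, classifying the item **appropriate** (*M* ≥ 6),
  **uncertain** (3 ≤ *M* < 6) or **inappropriate** (*M* < 3);
- the 30th and 70th centiles and the interpercentile range
  IPR = p70 − p30;
- the asymmetry index AI = |midpoint − IPRCP| with
  IPRCP = (p30 + p70)/2 and midpoint 4 on the 0–8 scale;
- the asymmetry-corrected disagreement threshold
  **IPRAS = IPRr + AI × CFA** (IPRr = 2.35, CFA = 1.5, the calibrated
  values for 9-point scales);
- the **disagreement index DI = IPR / IPRAS**; DI ≥ 1 means the panel
  disagreed.

Because everything from the centile pair onward is a closed-form function
of (median, p30, p70), the chain can be recomputed from a published summary
table alone — no raw ratings needed — and inconsistencies in printed tables
can be detected mechanically (`analyze_summaries()`).

The grading instrument applies the consensus decision rule to a study's
answers on five criteria (a-priori hypothesis; theory/evidence-driven
selection; pre-randomisation measurement; measurement quality; explicit
interaction test): all five satisfied ⇒ confirmatory; the final three ⇒
exploratory; any of the final three failed ⇒ excluded.

## Worked example

Recompute the appropriateness chain from a published first-round summary
table (bundled with the package) and analyze a raw polarized panel:

```r
library(randucla)

s <- analyze_summaries(panel_summaries(stage = "1"))
data.frame(item = s$item, median = s$median, p30 = s$p30, p70 = s$p70,
           DI = round_half_away(s$disagreement_index, 2),
           category = s$appropriateness, disagreement = s$disagreement)[1:5, ]
#>   item median p30 p70   DI    category disagreement
#> 1   1a    6.0   6   7 0.16 appropriate        FALSE
#> 2   1b    6.5   6   8 0.29 appropriate        FALSE
#> 3   2a    4.0   3   5 0.85   uncertain        FALSE
#> 4   2b    8.0   7   8 0.13 appropriate        FALSE
#> 5   3a    5.5   5   6 0.22   uncertain        FALSE

split_panel <- item_ratings("example", c(rep(0, 8), rep(8, 8)))
analyze_item(split_panel)
#> <item_statistics> item example (stage 1, n=16): median 4.0, centiles (0, 8),
#>   DI 3.4 -> uncertain, DISAGREEMENT
```

Item 1a: half the centile band sits one point wide (IPR 1) far above the
midpoint (AI 2.5), so the disagreement threshold is high (IPRAS 6.10) and
DI = 1/6.10 = 0.16 — a clearly endorsed item with no disagreement. The
16-rater split panel shows the opposite: centiles at the extremes give
IPR 8 against the minimal threshold 2.35, DI 3.40 — formal disagreement.

Grade a trial's moderator analysis:

```r
grade_study(study_appraisal("trial-A", list(
  criterion_answer("c1_a_priori", "no", "vague_hypothesis"),
  criterion_answer("c2_theory_evidence", "yes"),
  criterion_answer("c3_pre_randomisation", "not_applicable", "time_invariant_factor"),
  criterion_answer("c4_measurement_quality", "yes"),
  criterion_answer("c5_interaction_test", "yes"))))
#> <evidence_grade> trial-A: exploratory (failed: c1_a_priori)
```

The vague a-priori hypothesis blocks confirmatory status, but the three
core criteria hold (pre-randomisation measurement is waived for a
time-invariant factor such as sex), so the findings remain usable as
exploratory, hypothesis-generating evidence.

A shell entry point wrapping these functions ships in `inst/cli/consensus`
(subcommands `analyze`, `from-summaries`, `grade`, `simulate`).

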