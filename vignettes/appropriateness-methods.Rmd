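---
title: "Appropriateness statistics for consensus panels and moderator evidence grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appropriateness statistics for consensus panels and moderator evidence grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randucla)
```

## The problem

Expert consensus (Delphi) panels rate candidate items — here, methodological
criteria for appraising moderator (subgroup) analyses of randomised trials —
on a bounded integer scale, by default the 9-point scale 0 (completely
inappropriate) to 8 (extremely important). Two questions must be answered per
item: *is it appropriate?* and *did the panel actually agree?* A high median
can mask a split panel; a formal disagreement statistic is needed, and it must
work for panels of any (small) size, with per-item nonresponse.

`randucla` implements the RAND/UCLA appropriateness machinery for this
setting, plus the downstream deliverable of such a consensus: a five-criterion
instrument that grades a trial's moderator analysis as confirmatory,
exploratory, or excluded for meta-analysis.

## The statistic chain

For each item with ratings $x_1,\dots,x_n$:

* the **median** $M$ classifies appropriateness: appropriate if $M \ge 6$,
  inappropriate if $M < 3$, uncertain otherwise (thresholds live on the
  `rating_scale` and can be reconfigured);
* the 30th and 70th centiles give the **interpercentile range**
  $\mathrm{IPR} = p_{70} - p_{30}$;
* the IPR central point $\mathrm{IPRCP} = (p_{30}+p_{70})/2$ and the scale
  midpoint (4 on 0–8) give the **asymmetry index**
  $\mathrm{AI} = |\,\text{midpoint} - \mathrm{IPRCP}\,|$;
* the disagreement threshold is
  $\mathrm{IPRAS} = \mathrm{IPR}_r + \mathrm{AI} \times \mathrm{CFA}$,
  with $\mathrm{IPR}_r = 2.35$ and $\mathrm{CFA} = 1.5$, the values calibrated
  empirically for 9-point scales to reproduce the classic panel-size-bound
  disagreement definitions while applying to any panel size;
* the **disagreement index** is $\mathrm{DI} = \mathrm{IPR}/\mathrm{IPRAS}$;
  an index below 1.0 means no disagreement. We class exactly 1.0 as
  disagreement, since only "less than 1.0" is defined as agreement.

The rationale for the asymmetry correction: ratings bunched at one end of the
scale can show a wide IPR simply because the scale is bounded, so the
threshold beyond which spread means disagreement must grow as the ratings'
centre moves away from the scale midpoint.

```{r chain}
s <- statistics_from_percentiles("1a", 6.0, 6, 7)
s
c(ipr = s$ipr, iprcp = s$iprcp, ai = s$ai, ipras = s$ipras,
  di = round_half_away(s$disagreement_index, 2))
```

Two entry points compute the chain: `analyze_item()` / `analyze_round()` from
raw rating multisets, and `statistics_from_percentiles()` /
`analyze_summaries()` from printed summary statistics when — as is common for
published consensus studies — the raw ratings were never deposited. The chain
from the centile pair onward is identical in both modes, so the published
disagreement indices are reproducible from the published medians and centiles
alone, independent of the quantile estimator.

## Choices a user can change

* **Quantile estimator.** Published consensus tables rarely state one. The
  default is linear interpolation at rank $h = (n-1)p + 1$
  (`stats::quantile()` type 7), a common deterministic convention; nearest
  rank (type 1) is available via `engine_config(quantile_method =
  "nearest_rank")`. Summary-mode results do not depend on this choice.
* **Display rounding.** All statistics are kept at full precision internally;
  display rounds half away from zero (`round_half_away()`), 1 dp for medians
  and 2 dp for the disagreement index, matching how such tables are printed.
  Banker's rounding would print 0.125 as 0.12 and disagree with published
  values.
* **Category demotion.** By default the median alone sets the appropriateness
  category, and a disagreement verdict is reported alongside rather than
  overriding it (a published table we reproduce prints "Inappropriate" for an
  item with DI 1.09). The classic variant that demotes any disagreed item to
  "uncertain" is available as `engine_config(demote_disagreement = TRUE)`.
* **Small panels.** Items with fewer than `min_panel = 7` responses are still
  computed but flagged `unstable`; a hard error would block the very panel
  sizes (15–21) this method is designed for.
* **Missingness** is per-item deletion: an item's statistics use its observed
  ratings only. No imputation is offered, because none is defensible for
  anonymous panel ratings and published non-integer medians at odd nominal
  panel sizes show response counts genuinely vary by item.

## The consistency checker

`analyze_summaries()` recomputes the chain for every row of a printed summary
table and compares against printed disagreement indices and categories where
present. Two kinds of anomaly are kept distinct:

* `flagged` — the printed DI cannot be reproduced from the printed centiles
  (a numeric impossibility, e.g. a zero-width centile pair printed with a
  positive DI);
* `appropriateness_consistent = FALSE` — the printed category contradicts the
  median rule (e.g. a median of 5.5 printed as appropriate).

On the bundled published table (`panel_summaries()`) the checker flags
exactly two second-round rows on the numeric chain and one first-round row on
the category — see the package tests, which assert these counts.

## The synthetic-panel generator

With no raw ratings published, the pipeline is validated on synthetic panels
whose structure matches what the method assumes: small panels (default
`n_raters = 17`, the first-round panel size), independent discrete ratings,
and missing-at-random nonresponse. Profiles stipulate the rating
distribution:

* `consensus_high` / `consensus_low` — all mass on one extreme (degenerate by
  design, so classification recovery is exactly 1 and any failure is a bug);
* `indifferent` — uniform on the middle band 3..5, which forces
  $3 \le M < 6$ and an IPR of at most 2, hence always "uncertain" without
  disagreement;
* `polarized` — two camps: mass ½ on each extreme.

All generation is driven by one explicit integer seed; the same seed and
profiles regenerate byte-identical rounds. The generator deliberately has no
per-rater severity terms: the statistics are functions of the rating multiset
only (rater-exchangeable), so such structure would be untestable through the
engine.

`recovery_experiment()` reports the fraction of replicate panels whose engine
verdict matches the profile's designed category. One caveat is worth stating
precisely, because it is a property of the method, not a software artefact:
a polarized two-point panel shows formal disagreement only when both camps
are large enough that the 30th and 70th centiles land on (or near) opposite
extremes. For $n = 17$ raters split half/half at random, enumerating the
binomial count of minimum-ratings shows the disagreement verdict fires with
probability 0.857 (0.79 at $n = 16$; at no panel size between 15 and 21 does
it exceed 0.94). Random imbalance between the camps is simply not rare at
these panel sizes. The recovery tests therefore assert the exact enumerated
rate, within Monte-Carlo tolerance, rather than a near-certainty that the
statistic does not possess.

## The inverse search

`find_ratings_matching()` recovers a concrete rating multiset from a printed
summary row: the smallest (lexicographically first) non-decreasing vector of
$n$ in-scale integers whose median, centiles — after rounding to printed
precision (median 1 dp, centiles 0 dp) — and resulting disagreement index
(at display precision) reproduce the row. The search walks candidate vectors
depth-first with interval pruning at the order statistics that determine each
target, so exhausting the space is a proof of infeasibility. Degenerate
inputs short-circuit: targets with $p_{30} \le M \le p_{70}$ violated return
`NULL` immediately.

Infeasibility is informative. At odd $n$ the median is a single order
statistic and therefore an integer, so a printed median of 6.5 at a nominal
panel of 17 proves that item had an even number of responses — corroborating
per-item nonresponse without any access to the raw data. The round-trip test
over the bundled published table documents exactly this split: all
integer-median rows invert and reproduce their printed DI; all half-integer
stage-1 rows are proven infeasible at $n = 17$.

```{r inverse}
find_ratings_matching(17, 6.0, 6, 7)
find_ratings_matching(17, 6.5, 6, 8)       # NULL: impossible at odd n
find_ratings_matching(16, 6.5, 6, 8)[1:8]  # feasible with one nonresponse
```

## The grading instrument

The consensus' deliverable is five appraisal criteria for a trial's moderator
analysis: (1) an explicit a-priori hypothesis, (2) theory/evidence-driven
factor selection, (3) moderators measured before randomisation, (4) adequate
measurement quality, (5) an explicit moderator-by-treatment interaction test.
`grade_study()` applies the decision rule: all five satisfied is
**confirmatory**; the final three satisfied is **exploratory**; failing any
of the final three **excludes** the study. These three outcomes partition all
answer combinations, and improving any single answer never lowers the grade —
both properties are asserted exhaustively in the tests.

Implementation decisions where the instrument's published form was open:

* `not_applicable` is accepted only where a recognised exception exists —
  pre-randomisation measurement may be waived for time-invariant factors
  (e.g. sex) or cluster randomisation with measurement before allocation
  awareness — and a valid exception code is required; the exception then
  counts as satisfied.
* An `unknown` (not reported) response is accepted as input but never
  satisfies a criterion and never waives one: reviews meet unreported
  methods constantly and need to record them without inventing answers.
* A weak-theory judgment on criterion 2 demotes confirmatory to exploratory
  but can never exclude, which the grade rule guarantees structurally.
* Inadequate variability in the baseline measure is a failure code on
  criterion 4.
* Multiple appraisals of one study are stored side by side; no adjudication
  rule is imposed, since none was part of the consensus.

## Problem sizes and determinism

The test suite verifies the percentile estimators against an independent
brute-force oracle exhaustively over all 24,309 rating multisets of size up
to 8 and on 10,000 random larger multisets; the instrument's truth table is
exhausted (all answer combinations); recovery experiments use 200 replicates
per profile; the inverse search runs over all 15 chain-consistent published
rows in well under a second. Every stochastic operation takes an explicit
seed and restores the caller's RNG state, so results are reproducible to the
byte across runs and platforms.

## Limitations

* Synthetic profiles stipulate rating shapes; they are not estimates of any
  real panel's response distribution. Passing recovery tests shows the
  engine classifies the designed shapes correctly, not that real panels are
  so shaped.
* The generator models nonresponse as missing-at-random per rating;
  systematic nonresponse (e.g. dissenters abstaining) would bias any
  consensus method and is out of scope.
* Inter-rater reliability coefficients, Bayesian consensus models and rater
  weighting are deliberately not provided.
* The instrument automates the decision rule, not the appraisal itself:
  answering the five criteria for a given trial remains expert judgment.
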