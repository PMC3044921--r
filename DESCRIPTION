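Package: randucla
Title: RAND/UCLA Appropriateness Analysis for Consensus Panels and
    Moderator Evidence Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of expert consensus
    (Delphi) panels with the RAND/UCLA appropriateness method: per-item
    medians and interpercentile ranges, the asymmetry-corrected
    disagreement threshold (IPRAS) and disagreement index, and
    appropriateness classification on a bounded 9-point rating scale.
    Includes a consistency checker for published summary tables, a
    seeded generator of synthetic panels (consensus, indifferent and
    polarized response profiles with nonresponse), an exhaustive inverse
    search recovering rating multisets from printed summary statistics,
    and a five-criterion appraisal instrument that grades moderator
    (subgroup) analyses of randomised trials as confirmatory,
    exploratory, or excluded for meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
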