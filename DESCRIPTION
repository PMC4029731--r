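Package: alsclaims
Title: Diagnostic-Pathway Analysis of ALS in Quarterly Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based phenotyping and diagnostic-pathway analysis for
    amyotrophic lateral sclerosis (ALS) in quarter-granular administrative
    claims shaped like the CMS Medicare extracts: an ICD-9-CM symptom code
    catalog with wildcard matching, retrospective cohort construction with
    attrition tracking, first-symptom and onset-type calling, time-to-diagnosis
    estimation, pre-diagnosis prevalence rate ratios against a comparison
    cohort, diagnostic-test utilization tables, and a synthetic claims
    generator that emulates the source data structure so the full pipeline is
    testable without access to restricted claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
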