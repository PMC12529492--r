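Package: fdgclamp
Title: Tissue-Specific Insulin Sensitivity from FDG-PET and Euglycaemic Clamp Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whole-body and tissue-specific insulin sensitivity from
    hyperinsulinaemic-euglycaemic clamp records and dynamic [18F]FDG-PET
    time-activity curves: Gjedde-Patlak graphical estimation of the fractional
    uptake rate Ki, tissue glucose uptake via lumped constants, the clamp
    M-value, glucose rate of disappearance from tracer clearance, and
    endogenous glucose production. Also computes fasting and OGTT-derived
    insulin sensitivity and secretion indices (HOMA-IR, simplified Matsuda ISI,
    Adipo-IR), covariate-adjusted group comparisons with a graded evidence
    scale, a per-metabolite logistic association scan with Storey q-values, and
    noncentral-t sample-size calculations. A synthetic two-group cohort
    generator (low vs. mildly elevated liver-lipid content) emulates the data
    structure of combined PET/clamp/metabolomics studies so the full pipeline
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
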