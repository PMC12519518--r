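Package: prescreenr
Title: Blood-Based Biomarker Pre-Screening Simulation and Evaluation for
    Trial Enrichment
Version: 0.1.0
Authors@R:
    person("Maintainer", "prescreenr", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and evaluating blood-based biomarker (BBBM)
    pre-screening of secondary-prevention trial candidates. Simulates
    screening cohorts with carrier-stratified amyloid prevalence and
    log10-normal plasma biomarker distributions (pTau181, GFAP, Abeta42,
    Abeta40, ApoE4 protein), applies a two-step ApoE4p/pTau181 screen-out
    rule with a blinding pass-through, scores it against a composite
    PET/CSF amyloid reference with agreement metrics (PPA, NPA, PPV, 1-NPV,
    screen-out rate) and Wilson confidence intervals, transfers operating
    points to new prevalences by Bayes' rule, derives cutoff pairs under
    screen-out and 1-NPV acceptance constraints, and builds risk-percentile
    predictiveness curves with monotone smoothing and rank-based AUCs.
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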