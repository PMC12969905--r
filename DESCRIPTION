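Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for Two-Strategy
    Oncology Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-state partitioned survival model (progression-free,
    progressed disease, death) for cost-effectiveness analysis of a
    two-strategy oncology comparison, built around the second-line
    treatment decision for advanced endometrial carcinoma (lenvatinib
    plus pembrolizumab versus doxorubicin-based chemotherapy) under
    Taiwan's National Health Insurance. Provides six parametric survival
    families with maximum-likelihood fitting and information-criterion
    ranking, Kaplan-Meier estimation and pseudo individual-patient-data
    reconstruction from digitized curves with number-at-risk tables,
    hybrid Kaplan-Meier/parametric extrapolation, discounted cohort
    traces with per-state cost and QALY accrual, incremental
    cost-effectiveness statistics (ICER, net monetary benefit,
    acceptability curves, expected value of perfect information),
    one-way deterministic and probabilistic sensitivity analysis, a
    scenario engine, and a synthetic-data generator with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
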