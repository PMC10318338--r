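Package: mcdaid
Title: Multi-Criteria Decision Analysis with Pairwise Preference
    Elicitation and Probabilistic Sensitivity Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for additive multi-criteria decision analysis (MCDA) of
    competing interventions: criteria with ordered performance levels,
    performance matrices with red-amber-green rendering, unweighted and
    weighted additive scoring with tie-aware dense ranking, pairwise
    trade-off preference elicitation in the style of the PAPRIKA method
    (adaptive question selection, transitive-closure bookkeeping,
    ordinal-constraint solving for part-worth values, group aggregation),
    Dirichlet/gamma Monte Carlo probabilistic sensitivity analysis with
    first-rank acceptability, and synthetic-respondent generators for
    end-to-end simulation studies.  Ships a worked case study ranking four
    medication-optimisation intervention types for English NHS hospitals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
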