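Package: renalpk
Title: Renal Transporter Pharmacokinetics: Non-Compartmental Analysis and a
    Mechanistic Tubular Transport Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how changes in renal transporter expression
    alter drug disposition. Implements non-compartmental pharmacokinetic
    analysis of IV-bolus plasma, urine and kidney-tissue data (trapezoidal
    AUC, terminal-slope extrapolation, total and renal clearance, urinary
    recovery, kidney-to-plasma partition), the unbound-fraction and
    GFR-normalized renal clearance ratio used to classify net tubular
    secretion versus reabsorption, relative mRNA quantification by the
    delta-delta-Ct method, and cell-uptake assay reduction to
    percent-of-control. A mechanistic plasma/tubular-cell/lumen/urine
    simulator with flow-limited basolateral uptake, saturable apical efflux
    and saturable luminal reabsorption generates synthetic two-arm studies
    (control versus hyperuricemic-like transporter downregulation) for
    validating the analysis pipeline. Group statistics (mean with SEM,
    pooled-variance t test, Monte Carlo Dunnett many-to-one comparisons)
    and tidy CSV input/output round out the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
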