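Package: qtcda
Title: Decision Analysis of Antipsychotic Choice for Delirium with QTc Prolongation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expected-utility decision analysis comparing antipsychotic drugs
    for delirium in patients with prolonged baseline QTc intervals. Ingests
    per-drug effect tables (delirium-improvement odds ratios with 95%
    confidence intervals and mean QTc shifts in milliseconds), converts odds
    ratios to transition probabilities against a placebo response rate,
    values health states with QTc-dependent sigmoid utility curves (plus
    linear and exponential risk-attitude variants), evaluates a two-branch
    decision tree across a grid of baseline QTc values, and propagates
    effect-size uncertainty with a Monte Carlo probabilistic sensitivity
    analysis cross-checked by Gauss-Hermite quadrature. Includes
    deterministic utility-parameter sensitivity sweeps, a synthetic
    effect-table generator for simulation studies, and CSV report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
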