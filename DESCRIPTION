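Package: opbias
Title: Operational-Model Bias, Furchgott Efficacy and Desensitisation Analysis for Opioid Concentration-Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pharmacology toolkit for agonist signalling-bias
    studies at the mu opioid receptor and other GPCRs. Fits four- and
    three-parameter logistic concentration-response curves per experiment and
    pooled, fits the Black-Leff operational model to obtain Log(tau/KA)
    transduction ratios and DeltaDeltaLog(tau/KA) bias factors against a
    reference agonist with Dunnett-adjusted comparisons, implements the
    Furchgott irreversible-antagonist method (equieffective-concentration
    pairing, KA and q estimation, occupancy and receptor-reserve summaries),
    and quantifies desensitisation of GIRK current traces by one-phase decay
    fitting. A synthetic-data generator produces BRET-style assay datasets and
    current traces from operational-model ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
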