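Package: dtxcua
Title: Trial-Based Cost-Utility Analysis and Value-Based Pricing for
    Digital Therapeutics in Pulmonary Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Economic evaluation toolkit for an 8-week randomized trial of a
    digital therapeutic (DTx) for pulmonary rehabilitation in chronic
    respiratory disease.  Maps COPD Assessment Test (CAT) item scores to
    EQ-5D-3L utilities with a published ordinary-least-squares algorithm,
    accumulates quality-adjusted life years (QALYs) by the trapezoid rule,
    computes incremental cost-utility ratios and net monetary benefit,
    derives the value-based price of the DTx usage fee under a
    willingness-to-pay threshold, runs probabilistic (gamma/normal) and
    one-way deterministic sensitivity analyses with cost-effectiveness
    acceptability curves, extrapolates to one year with a five-state Markov
    cohort model on the mMRC dyspnea scale, and ships a synthetic
    patient-level trial generator so every stage is reproducible without
    access to the original trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
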