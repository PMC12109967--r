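Package: tnfiRS
Title: Predicting Clinical Response to TNF Inhibitors from tmTNF
    Reverse-Signaling Nrf2 Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a theranostic RT-qPCR assay for predicting the
    3-month clinical response of rheumatoid arthritis patients to
    monoclonal TNF inhibitors. Raw cycle-threshold (Ct) tables for CD36
    and six Nrf2 target genes are turned into treated/untreated
    fold-change ratios normalized to GAPDH (2^-ddCt), donors are
    classified as tmTNF reverse-signaling activators or non-activators
    by a coefficient-of-variation-calibrated decision band, clinical
    response is classified from DAS28 using the EULAR grid, and
    prediction-outcome concordance is scored per drug class. A
    Ct-level cohort simulator with calibrated replicate noise and
    amplification dropout supports validation without patient samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
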