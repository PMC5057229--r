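Package: ncounterDE
Title: Differential miRNA Expression Analysis for NanoString nCounter Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing and two-group differential-expression analysis for
    NanoString nCounter miRNA count data: positive-control lane scaling,
    negative-control background thresholding (mean + k*SD), prevalence
    filtering, quantile normalization, per-miRNA linear-model testing with an
    expected-false-positive significance cutoff (alpha = 1/m), signed fold
    changes, and supervised hierarchical clustering of the resulting
    signature. Includes a comparative-Ct (delta-delta-Ct) relative
    quantification layer for qPCR validation with one-way ANOVA, and a
    negative-binomial synthetic-data generator with planted ground truth for
    end-to-end testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
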