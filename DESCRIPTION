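Package: meltshift
Title: Thermal Shift Scoring and Target Deconvolution for MS-CETSA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for proteome-wide cellular thermal shift
    assay (MS-CETSA) experiments. Normalizes per-protein fold-change
    melting data across a ten-point temperature gradient using a
    median-profile fitting-factor vector and scaling factor, fits
    four-parameter log-logistic melting curves, scores compound-induced
    thermal shifts with a Euclidean-distance (ED) score penalized by
    replicate disagreement and a melting-point shift (delta Tm) at the
    0.5 fold-change level, and selects target hits with robust
    median + k*MAD cutoffs. Includes a synthetic-data generator with
    known ground truth (spiked thermally stabilized targets, non-melters,
    early melters, run-level distortions) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
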