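Package: revsig
Title: Personalized Drug Repurposing by Reversal of Individual Disease Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an individual disease signature for a single tumor
    expression profile by consensus NMF subtyping of a reference cohort,
    subgroup replicate selection, optional tumor-purity deconvolution and
    differential expression, then scores a drug perturbation library for
    signature reversal with Kolmogorov-Smirnov connectivity statistics
    (RGES) summarized per drug (sRGES), and validates predictions in
    silico against cell-line drug-sensitivity data with correlation,
    t-test, permutation-null and ROC analyses. Includes a synthetic-data
    generator emulating the statistical structure of the real inputs so
    the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
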