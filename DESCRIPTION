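Package: dhmlipid
Title: Label-Free Lipid Droplet Quantification from Digital Holographic
    Microscopy Phase Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies adipocytic differentiation from quantitative phase
    images without staining. Provides a ground-truthed synthetic generator of
    optical-path-difference (OPD) fields of differentiating adipocytes, robust
    fixed-threshold and Ridler-Calvard segmentation, per-cell morphological and
    OPD feature extraction, rule-based and machine-learning phenotype
    classification (undifferentiated, adipocytic, dead), well-level
    aggregation, a fluorescence comparison branch (illumination correction,
    nucleus-anchored lipid intensity, Nile Red cytoplasm masks, ethidium
    homodimer dead-cell fractions), and screening statistics: Z-prime factors,
    linear correlation, and four-parameter logistic dose-response fitting with
    IC50 censoring, including end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    randomForest,
    class,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
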