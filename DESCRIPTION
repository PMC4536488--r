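Package: codeit
Title: Quantification of Contact-Dependent Intercellular Transfer in 3D Co-Culture Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A microscopy-based screening toolkit for quantifying
    contact-dependent intercellular transfer (codeIT) between a single
    dye-labelled donor cell and a confluent lawn of acceptor cells.
    Provides CellSegm-style 3D cell segmentation from a membrane stain
    (anisotropic filtering, nucleus-based marker generation,
    marker-controlled watershed, region classification), automatic
    donor-cell recognition with volume and morphology filters, per-cell
    quantification of supra-threshold transferred signal with donor
    blanking and boundary/volume exclusions, acquisition-side region-of-
    interest selection over tiled well mosaics, and the accompanying
    statistics (normalization to the control median, natural-log
    transform, chi-square normality test, ANOVA with Dunnett post-hoc
    comparisons, t-tests). A synthetic-data generator with complete
    ground truth makes the whole pipeline testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    multcomp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
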