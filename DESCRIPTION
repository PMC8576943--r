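Package: clonescape
Title: Multiregional Tumor Heterogeneity, Clonality and Neutral-Evolution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multiregional tumor sequencing data: somatic variant
    filtering with cross-sample recovery, intratumoral heterogeneity statistics
    (sharing spectra, single-sample miss rates, multi-hit genes, copy-number
    heterogeneity), cancer-cell-fraction based clonal/subclonal classification
    per sample and per patient, the 1/f neutral-evolution test with R-squared
    and Kolmogorov distance, exact maximum-parsimony trees over tumor regions
    via branch and bound, immunohistochemistry H-scores, and estimation of the
    number of regional samples needed for reliable clonal identification. A
    bundled simulator generates synthetic multiregional tumors with known
    clonal structure so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
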