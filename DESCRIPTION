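Package: homeoTSS
Title: Homeolog Expression Partitioning and Tissue-Specific Silencing in
    Newly Formed Polyploids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing allele-specific (homeolog-specific)
    expression assays in hybrids and synthetic allopolyploids, as measured
    by known-SNP allelotyping platforms such as Sequenom MassARRAY.
    Includes calibration quality control against known DNA mix ratios,
    classification of relative homeolog expression into biased-expression
    categories, detection and scoring of tissue-specific silencing (TSS),
    reciprocal TSS (subfunctionalization) and nonfunctionalization across
    tissues and growth stages, nonparametric group comparisons, and a
    synthetic-data generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
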