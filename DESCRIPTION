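Package: meioscan
Title: Meiotic Crossover Interference, Univalent Segregation, and
    Bulked-Segregant Mapping
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for cytogenetic and mapping analyses of
    meiotic mutants. Summarises per-meiocyte chiasma counts scored from
    bivalent morphology, tests crossover interference by comparing the
    chiasma-count distribution against its Poisson prediction with a
    discrete Kolmogorov-Smirnov test (parametric-bootstrap calibrated),
    computes crossover/bivalent reduction percentages, models residual
    fertility under random univalent segregation, tests Mendelian
    segregation ratios, and performs a bulked-segregant-analysis
    (BSA-seq) SNP-index scan with sliding windows and candidate-region
    calling from a bulk VCF. A forward meiosis-I simulator (obligate
    interfering Class I plus Poisson Class II crossover pathways) and
    synthetic-data generators make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    optparse,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
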