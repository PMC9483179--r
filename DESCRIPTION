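Package: rrmgwas
Title: Random-Regression Test-Day Models and Multi-Locus GWAS for Dairy Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for longitudinal dairy-cattle
    test-day records. Generates multi-generation pedigrees, gene-dropped SNP
    genotypes and test-day phenotypes for six milk production traits (milk,
    fat and protein yield, fat and protein percentage, somatic cell score);
    derives somatic cell score and component yields and applies standard
    record- and cow-level inclusion criteria; builds numerator relationship
    matrices with optionally depth-capped inbreeding; fits single-trait
    random-regression test-day models on a Legendre polynomial basis by
    EM-REML to obtain days-in-milk specific heritabilities, genetic
    correlations and breeding-value trajectories; and scans DIM-specific
    breeding values for associations with a P3D mixed linear model and a
    FarmCPU-style multi-locus procedure, annotating significant variants
    against gene and QTL interval tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
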