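Package: ndcoloc
Title: Ancestry-Aware Colocalisation of Neurodegenerative-Disease GWAS and
    Immune-Cell eQTL Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links expression of neurodegenerative-disease genes in
    peripheral immune cells to disease risk across ancestries. Provides
    tau expression-specificity statistics over cell types and viral
    activation states, reading and harmonisation of GWAS and eQTL summary
    statistics (allele alignment, strand flips, palindromic-SNP filtering,
    locus windowing), a Bayes-factor colocalisation engine with five
    posterior hypotheses and power-aware decision rules, effect-direction
    analysis at colocalised loci, and an LD-structured simulator of paired
    summary statistics and multi-cell-type expression matrices for
    calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
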