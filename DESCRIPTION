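Package: vertitrace
Title: Evidence Chain for Vertical Inheritance Versus Lateral Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for testing whether a bacterial gene was vertically
    inherited or laterally acquired, combining composition-based screens
    (GC deviation of the gene against its genome, Z-curve quadratic-
    divergence genome segmentation), selection analysis (pairwise
    Nei-Gojobori dN/dS against a core-gene background with a two-sided
    bootstrap equality-of-means test), trait evolution on a dated species
    tree (maximum-likelihood Mk ancestral-state reconstruction, gain/loss
    counting, origin-node inference, calibration-based node dating,
    gene-tree/species-tree incongruence flagging), gene-neighbourhood
    synteny scoring and protein-variant subtyping. A synthetic-data module
    generates genomes with compositional islands, codon pairs evolved at a
    known omega, binary traits on trees, engineered transfers and protein
    variant sets with controlled identity structure, so every stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
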