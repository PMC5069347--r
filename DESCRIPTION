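Package: ryegp
Title: Genomic and Pedigree-Based Prediction Across Hybrid Rye Breeding Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genome-based prediction in a
    multi-cycle hybrid rye breeding program. Provides a synthetic breeding-program
    generator (founder haplotypes, meiosis with Haldane recombination, single-seed
    descent, testcross trials in alpha-lattice designs), SNP quality control and
    linkage-disequilibrium analysis, pedigree and marker-based relationship
    matrices with explicit selfing-generation accounting, two-stage analysis of
    multi-environment testcross trials with weighted stage-2 mixed models and
    progeny-mean heritability, REML fitting of GBLUP and PBLUP models via kernel
    eigendecomposition, and within- and across-cycle cross-validation designs
    with heritability-corrected prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
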