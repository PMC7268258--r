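Package: catchn
Title: TnSeq Depletion Statistics and Bioenergetics of the CATCH-N
    Nitrogen-Fixation Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for in-planta transposon sequencing (TnSeq)
    screens of symbiotic nitrogen fixation and for the bioenergetic and
    kinetic modelling of the CATCH-N cycle, the co-catabolism of
    plant-provided arginine and succinate by rhizobial bacteroids.
    Provides per-gene essentiality calls from insertion density and gap
    structure; a symbiosis impairment score combining a Poisson recovery
    probability with an exact run-length combinatorics term for
    contiguous insertion loss; stoichiometric ATP, proton, oxygen and
    nitrogen budgets for candidate nitrogen-fixation pathways driven by a
    bifurcated electron transport chain; a mass-action model of the
    arginine transamination reaction network with isotope-label
    propagation; and a synthetic-data generator producing annotated
    genomes and insertion libraries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    deSolve,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
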