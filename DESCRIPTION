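Package: rhizokmer
Title: k-mer Based Association Analysis of Rhizobium Nodulation Competitiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links pairwise competition phenotypes of rhizobia (nodule occupancy
    of fluorescently tagged strains on legume roots) to genomic determinants.
    Implements a genome-wide association procedure on canonical 13-mer
    presence/absence profiles with clonal population-structure correction
    (Jaccard distances, UPGMA clustering, Gerstein-Sonnhammer-Chothia sample
    weights) and a weighted Welch two-sample t-test per k-mer; an L1-regularized
    regression with nested cross-validation for phenotype prediction; and
    annotation of significant k-mers against genome features (coding sequences,
    regulatory windows upstream of CDS starts, replicon distribution). A
    synthetic-data generator produces multi-replicon genomes, GFF3 annotations,
    competition phenotypes and per-plant nodule count tables with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
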