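Package: crenadelim
Title: Integrated Allozyme and Mitochondrial Species Delimitation for the
    Crenadactylus Gecko Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilocus delimitation of cryptic species in the
    Australian clawless geckos (Crenadactylus), and in comparable codominant
    marker datasets.  Implements stepwise Principal Co-ordinates Analysis of
    Rogers' genetic distances with fixed-difference validation of clusters
    (allowing a cumulative shared-allele tolerance), Nei's unbiased genetic
    distance, private-allele diagnosis, pairwise mitochondrial divergences
    (uncorrected and model-corrected), reciprocal-monophyly assessment on gene
    trees, and a congruence rule that elevates validated clusters to candidate
    species.  Includes a seeded synthetic-data generator that plants known
    group structure in allozyme genotype tables and sequence alignments so
    every pipeline stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
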