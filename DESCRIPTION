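Package: foldtree
Title: Structure-Based Phylogenetics from All-Versus-All Structural Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phylogenetic trees from all-versus-all structural
    alignment similarity tables. Pairwise similarity scores (Fident, LDDT
    or alignment-length-normalised TM score) are converted to evolutionary
    distances by a saturation-inverting correction, trees are inferred by
    neighbor joining and rooted by minimal ancestor deviation (MAD). Tree
    quality is evaluated with a Taxonomic Congruence Score against leaf
    lineages and with the variance of normalised root-to-tip distances.
    Includes consensus-core trimming of homolog sets (corecut) with
    clustering of the trimmed termini, and a seeded synthetic-data
    generator (trees, taxonomies, alignment tables, structures) so every
    stage can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
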