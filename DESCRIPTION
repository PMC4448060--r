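Package: cliquecell
Title: Cell-Type Similarity Analysis of Spatial Gene-Expression Cliques
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links sets of co-expressed genes ("cliques") to cell types in a
    voxelized gene-expression atlas. Estimates nonnegative cell-type density
    fields by per-voxel nonnegative least squares against a panel of
    cell-type transcriptomes, ranks cell types by cosine similarity between
    their density profiles and the summed expression profile of a gene
    clique, assesses significance with a Monte Carlo null over random gene
    sets sized by Hoeffding's inequality, sweeps an expression threshold to
    contrast candidate cell types, fits clique profiles with optimal
    nonnegative combinations of pairs of density profiles, and scores
    density profiles against anatomical region masks. Includes a synthetic
    atlas generator with planted marker structure so the whole pipeline is
    testable end-to-end with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
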