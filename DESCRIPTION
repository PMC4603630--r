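Package: adjevol
Title: Probabilistic Evolution of Gene Adjacencies on Reconciled Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood reconstruction of ancestral gene orders from
    extant gene adjacencies and reconciled gene trees. Extant adjacencies are
    clustered into homology classes, each class is expanded into a tree of
    possible adjacencies whose nodes are same-species pairs of gene-tree nodes
    (with duplication nodes and loss leaves), and a two-state birth/death
    Markov model with duplication-integrated transition kernels is run on
    these trees by Felsenstein pruning. The package optimizes the gain/loss
    ratio, the root presence probability and the species-tree branch lengths,
    computes posterior probabilities of presence for every possible ancestral
    adjacency, provides a Sankoff parsimony baseline for comparison, and ships
    a full synthetic-data generator that simulates reconciled gene families
    and adjacency histories under the same generative process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
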