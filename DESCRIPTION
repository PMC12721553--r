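Package: PhyloAR
Title: Autoregressive Generative Models over Phylogenetic Tree Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Autoregressive probabilistic modeling of unrooted bifurcating
    tree topologies by sequential leaf attachment. Topological node
    embeddings are obtained by minimizing the Dirichlet energy with a
    provably contracting fixed-point iteration (with a repeated-squaring
    "power trick"), and edge-attachment distributions are formed with
    attention-based global pooling over node features. Supports three
    training tasks: variational maximum parsimony with an annealed
    multi-sample bound and the VIMCO gradient estimator, tree-topology
    density estimation by maximum likelihood, and variational Bayesian
    phylogenetic inference under the Jukes-Cantor substitution model with
    a lognormal branch-length family. Includes exact small-tree
    enumeration, Fitch parsimony, Felsenstein pruning, and synthetic-data
    generators (posterior-style tree sets and simulated alignments) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
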