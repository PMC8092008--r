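Package: wgtloss
Title: Phylogenetic Models of Biased Gene Loss After Whole-Genome
    Triplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the fate of gene copies created by an ancient
    whole-genome triplication (hexaploidy). A seven-state continuous-time
    Markov chain describes biased fractionation of the three parental
    subgenomes, including a two-step allopolyploidy model in which the
    least-fractionated subgenome arrives after the first hybridization.
    A hidden Markov chain over syntenic pillars infers, by Felsenstein
    pruning along a species tree, which syntenic track in each descendant
    genome derives from which parental subgenome.  The package also
    provides nested likelihood-ratio model comparison, triple-conserved
    synteny pillar construction by simulated annealing, ancestral gene
    order reconstruction by maximum-weight matching, permutation and
    degree-preserving rewiring tests for subgenome structure in
    interaction and coexpression networks, and generators for synthetic
    data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
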