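Package: netmmmc
Title: Multiple-Membership Multiple-Classification Models for Social
    Network and Group Dependences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Jointly estimates social-network, school and area dependences
    in an individual-level continuous response using multiple-membership
    multiple-classification (MMMC) random-effects models fitted by Gibbs
    sampling, with the deviance information criterion for model comparison.
    Provides tools to turn friendship nomination data into directed and
    symmetrized adjacency matrices, ego-nets and maximal cliques; to build
    the membership weight matrices that link individuals to network
    subgroup random effects; to fit the competing network autocorrelation
    (effects, disturbances and combined) models by maximum likelihood; to
    partition response variance across classifications using average
    membership weights; and to simulate populations with the sampled-network
    structure (isolates, capped nominations, schools crossed with areas)
    these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
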