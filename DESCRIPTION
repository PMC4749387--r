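Package: ontogram
Title: Cladistic Ontogeny Analysis of Cranial Sutural Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds ontograms: single-species trees obtained by applying
    maximum parsimony to ontogenetic characters describing the degree of
    closure and interdigitation of cranial sutures and skull-base
    synchondroses, rooted on a hypothetical all-immature embryo. Provides
    NEXUS character-matrix input/output with polymorphic multistate cells,
    heuristic tree search (random addition plus tree-bisection-reconnection
    branch swapping), strict and majority-rule consensus, nonparametric
    bootstrap support, ensemble consistency/homoplasy/retention indices,
    ACCTRAN ancestral-state reconstruction and extraction of the sutural
    obliteration sequence. Also implements numeric suture-closure scoring
    with specimen, ontogenetic-category and anatomical-group averages and
    size-closure trend fits, a histomorphometric sutural-width statistic
    (sectional area over trace length) with skull-length normalization,
    inter-rater reliability (Cohen's kappa with null-hypothesis Z, Pearson
    correlation), and a synthetic ontogenetic-series generator for
    closing-type and widening-type sutural trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
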