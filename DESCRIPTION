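Package: expclad
Title: Parsimony Cladistics of Gene Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polarizes gene expression matrices against an outgroup of
    reference specimens into ancestral and derived states, infers
    most-parsimonious cladograms from the resulting binary matrix under
    Wagner or Camin-Sokal parsimony, extracts and maps clade synapomorphies
    (shared derived expression states), detects dichotomously expressed
    asynchronous (DEA) genes, and validates the whole chain on synthetic
    expression data with planted phylogenetic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
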