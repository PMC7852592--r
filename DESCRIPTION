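Package: penBLUP
Title: Genetic Evaluation from Group-Recorded Phenotypes with Pedigree and
    Genomic Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and genetic evaluation of traits recorded at the
    group (pen) level rather than on individuals, as for feed intake in
    group-housed pigs. Provides a forward-in-time population simulator with
    linkage disequilibrium, litter/pen structure and pen-summed records;
    pedigree (A), genomic (VanRaden G), blended and single-step (H)
    relationship matrices; Henderson mixed-model equations for univariate
    and bivariate animal models in which one trait may be recorded as
    pen sums; average-information REML estimation of (co)variance
    components; and validation tooling (accuracy and dispersion bias of
    estimated breeding values against simulated true breeding values).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
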