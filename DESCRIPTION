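Package: ratchetwave
Title: The Boundary Between Adaptation and Muller's Ratchet in Rapidly Evolving Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theory and simulation of the balance between beneficial and
    deleterious mutation accumulation in rapidly evolving asexual
    populations. Implements fixation probabilities under the moderate
    selection, strong mutation (MSSM) traveling-wave approximation, the
    implicit solver for the coalescence timescale Tc, the v=0 / F=U /
    alpha=0 surfaces in scaled and unscaled parameter space (including
    ridgelines and an Ne-based heuristic for strong purifying selection),
    an individual-based Wright-Fisher forward simulator with tracked
    mutations and heterozygosity-based estimators, and fitness-mediated
    epistasis dynamics (diminishing-returns and increasing-costs flows
    through parameter space).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
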