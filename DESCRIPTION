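Package: memstrat
Title: Optimal Specificity and Deliberation of Immune Memory Against Evolving Pathogens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-theoretic model of immune memory as a tested simulation
    pipeline. Receptor energetics follow an affinity/cross-reactivity tradeoff
    kernel over a one-dimensional antigenic shape space; the choice between a
    stored memory and a novel naive response is a maximum-entropy decision whose
    sub-optimality is priced as a Kullback-Leibler dissipation. The package
    simulates lifetimes of re-infections with antigenically drifting pathogens,
    optimizes memory strategies (specificity and deliberation) by grid search,
    optimizes mixtures of specificities by stochastic gradient ascent, and maps
    how optimal strategies depend on antigenic divergence and host life
    expectancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
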