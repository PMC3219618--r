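Package: autocircuit
Title: Deterministic and Stochastic Analysis of Inducible Auto-Activating Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of transcription circuits in which a post-translationally
    activated transcription factor (such as a two-component response regulator)
    activates its own expression. Provides the Hill-type deterministic rate
    model (steady states, response curves, bistability phase diagrams, the
    closed-form critical fold change), log-log sensitivity measures with exact
    closed forms and open-loop comparisons, a burst-production chemical master
    equation on a truncated copy-number lattice (stationary distributions,
    bimodality detection, exact mean induction times via first-passage linear
    solves), an exact stochastic simulation algorithm, and the synthesis of
    these constraints into admissible-parameter-region maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
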