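Package: protocellsim
Title: Lattice Multiset Chemical Simulation of Protocell Emergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator of an artificial chemistry on a periodic
    hexagonal lattice in which cell-like compartments emerge, replicate and
    metabolize. Fifteen virtual molecular species diffuse by per-species
    residual rates and react by multiset rewriting rules inside each lattice
    cell; two polymer types (an information polymer encoding a morphology
    parameter as a monomer ratio, and a membrane polymer whose spatial
    density defines the compartment) couple the reaction network to a
    Turing-type activator-inhibitor patterning rule. Includes configuration
    (morphological) entropy and entropy-production accounting, pattern
    metrics (domain masks, connected components, qualitative pattern
    classification), and a discretized cellular-automaton reference model
    for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
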