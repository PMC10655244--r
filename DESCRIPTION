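Package: ringstack
Title: Simulation and Analysis of Semiflexible Polyelectrolyte Ring Solutions
Version: 0.1.0
Authors@R:
    person("Ringstack", "Developers", email = "ringstack@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained Langevin dynamics of charged semiflexible ring
    polymers (DNA mini-ring like) with explicit counterions, together with the
    analysis pipeline for such solutions: gyration-tensor shape descriptors
    (radius of gyration, prolateness, director), geometric stack-cluster
    identification, static structure factors and intermediate scattering
    functions between ring centres of mass, radial distribution functions and
    counterion-condensation diagnostics, and minimal-surface based threading
    analysis. Includes planted-truth synthetic scene generators so every
    analysis stage is testable without molecular dynamics, plain-text
    trajectory formats (XYZ, LAMMPS dump, native), and a small command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
NeedsCompilation: yes
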