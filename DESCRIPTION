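Package: tumormg
Title: Adaptive Nonlinear Multigrid Simulation of Desmoplastic Tumor Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates three-dimensional multispecies desmoplastic tumor
    growth with a diffuse-interface (Cahn-Hilliard type) mixture model on a
    block-structured, adaptively refined Cartesian mesh.  Each Crank-Nicolson
    time step is solved by a fully adaptive nonlinear full-multigrid (FMG)
    algorithm built on Full Approximation Scheme (FAS) V-cycles with
    Red-Black Gauss-Seidel relaxation.  Includes signature-based block
    clustering of flagged cells, inter-grid transfer operators (averaging
    restriction, trilinear prolongation, quadratic ghost fill, cubic FMG
    interpolation), quasi-steady reaction-diffusion solvers for nutrients and
    tumorigenic factors, Darcy pressure/velocity solves, manufactured-solution
    fixtures, and a convergence-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
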