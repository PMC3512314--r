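Package: pullwork
Title: Nonequilibrium Work Analysis of Steered Ligand-Unbinding Pulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating ligand-unbinding free-energy bounds from
    steered-pull trajectories. Reads and writes GROMACS-pull-style XVG force
    and position traces, integrates mechanical work per replica, computes the
    plain work average and the finite-sampling Jarzynski estimator with
    bootstrap errors, applies a viscous-dissipation correction from a
    receptor-free control, derives free energies from experimental affinity
    constants, and provides replica-averaged force profiles with an
    error-bar-crossing convergence criterion, a binding-pocket-plane region
    partition, and work-histogram population summaries. A steered overdamped
    Langevin generator with an exact quadrature free-energy oracle validates
    the whole chain on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
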