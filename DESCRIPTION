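Package: rbfekit
Title: Setup and Analysis Toolkit for Spherical-Boundary Relative Binding
    Free Energy Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational stages of dual-topology relative
    binding free energy (RBFE) workflows run under spherical boundary
    conditions: Cartesian-overlap atom mapping between congeneric ligands
    with ring-based sanity filters, automated cross-topology distance
    restraint generation via a hierarchical atom-equivalence criterion,
    solvated-droplet system construction, sigmoidal lambda-window
    scheduling, Bennett acceptance ratio (BAR) free energy estimation with
    replicate statistics, cycle-closure correction of perturbation
    networks by global least squares, and benchmark metrics (Kendall tau,
    MUE, bootstrap confidence intervals, Mann-Whitney U tests with Holm
    correction). Molecular dynamics itself is out of scope; synthetic
    fixture generators allow the whole pipeline to run and be tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
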