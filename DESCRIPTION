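Package: mcdock
Title: Multicanonical Dynamic Docking and Umbrella-Sampling Binding Free
    Energies for Coarse-Grained Receptor-Ligand Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage binding methodology for coarse-grained
    receptor-ligand models: multicanonical (flat-histogram) Monte-Carlo
    docking inside a cylindrical center-of-mass restraint, followed by
    umbrella sampling along the cylinder axis, the weighted histogram
    analysis method (WHAM), and a standard-state volume correction that
    converts the potential-of-mean-force depth and the Boltzmann-weighted
    site volume into a standard binding free energy. Includes a Go-model
    toy receptor-ligand generator with analytic harmonic references used
    as oracles, canonical reweighting, weighted PCA free-energy
    landscapes with basin clustering, native-contact R-value statistics,
    RMSD/RMSF analysis, and dynamic-programming selection of
    binding-pathway seed structures whose interface contact matrices
    change slowly along the pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
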