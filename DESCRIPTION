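Package: saxsbm
Title: Scattering-Guided Structure-Based Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: All-atom native structure-based (Go-type) molecular dynamics with
    a differentiable small-angle X-ray scattering (SAXS) bias. Builds
    structure-based topologies from native protein structures, computes
    residue-level Debye scattering intensities with analytic coordinate
    gradients, adds a chi-square bias potential toward difference-scattering
    targets, and integrates Langevin dynamics in reduced units. Includes
    synthetic two-state fixtures, target-data generation with realistic
    counting noise, and trajectory analysis (Kabsch RMSD, gyration tensor,
    end-to-end statistics, bias/RMSD correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
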