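Package: crowdsolv
Title: Solvation Structure, Thermodynamics and Ion Distributions from
    Molecular Dynamics Trajectories of Nucleic Acids in Crowded Solvents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of a
    nucleic-acid solute in mixed water/crowder/salt solvents.  Computes
    pair-correlation functions with bulk-density normalization and
    trapezoid coordination numbers, geometric hydrogen-bond networks with
    local/whole-system normalization and maximum lifetimes, solvation-shell
    occupancy, water-replacement statistics and residence times, mean
    squared displacement diffusion coefficients, voxel-based inhomogeneous
    solvation (GIST-style) thermodynamics with OpenDX density export,
    curvilinear-helicoidal ion density maps and groove occupancies, and
    DNA structural metrics (superposition RMSD/RMSF, groove widths,
    bending, essential-dynamics PCA and eigenvector similarity indices).
    Includes synthetic-trajectory generators with analytically known
    statistics for validating every estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
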