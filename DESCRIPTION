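Package: fablens
Title: Structural and Ensemble Analysis of Antibody Fab Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing antibody Fab crystal structures and relating
    simulated conformational ensembles to solution small-angle X-ray scattering
    (SAXS) data. Implements pseudo-twofold (pseudo-dyad) axis fitting and Fab
    elbow angles, Kabsch rigid-body superposition with matched-residue RMSD and
    windowed per-domain RMSF, Shrake-Rupley solvent-accessible surface area
    aggregated over aggregation-prone regions, radius of gyration and trajectory
    summary statistics with SEM over repeats, Debye-equation SAXS profiles with
    reduced chi-square ensemble fitting and best-fit frame extraction, and a
    synthetic-data generator that builds Fab-like structures, hinge-motion
    trajectories and noisy SAXS curves with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
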