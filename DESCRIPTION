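Package: hepareg
Title: Volume-to-Surface Registration Evaluation for Hepatic Soft-Tissue Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for non-rigid volume-to-surface registration of
    deformable organs, as used in laparoscopic liver navigation. Provides triangle
    and tetrahedral mesh containers with STL/PLY/OFF/VTK input and output,
    centre-of-mass plane bisections for building partial target surfaces,
    manifoldness diagnostics and two automatic mesh repair strategies, a
    physics-based shape-matching registration that deforms an electrically
    charged linear-elastic tetrahedral volume into an oppositely charged rigid
    target surface, solid voxelization onto a shared uniform grid, a voxel and
    mesh metric suite (Hausdorff distance, Jaccard, adjusted Rand index, mutual
    information, sensitivity, specificity, precision, RMSE), a synthetic
    deformable liver phantom with known ground-truth displacements, and drivers
    for orientation, mesh-quality and surface-size experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
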