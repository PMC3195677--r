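Package: trabl
Title: Total Radial Acetabular Bone Loss Quantification from Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies acetabular bone deficiency for hip revision planning
    by radial ray casting from the reconstructed joint center against a
    deficient and an anatomically reconstructed hemipelvis surface mesh.
    Produces a planar azimuthal-equidistant deviation map, a total radial
    acetabular bone loss (TrABL) ratio overall and per anatomical subregion
    (five sectors about the anteroposterior axis plus a medial cap), cohort
    summaries, and color-graph / radar visualizations. Includes STL mesh
    input/output, least-squares sphere and plane fitting, an ISB-based
    pelvic coordinate frame, and a synthetic phantom generator with known
    ground-truth defects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
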