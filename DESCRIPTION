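Package: cytoarch
Title: Observer-Independent Cytoarchitectonic Mapping Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical pipeline for observer-independent cytoarchitectonic
    parcellation of the cerebral cortex. Computes Grey Level Index (GLI)
    images from binarized cell-body images, extracts depth-normalized laminar
    profiles along Laplacian streamlines between cortical contours, and
    detects area borders as significant maxima of a sliding-window
    Mahalanobis distance between blocks of profile feature vectors (Hotelling
    T-squared test, Bonferroni corrected, consensus over block sizes).
    Further stages estimate shrinkage-corrected areal volumes by the
    Cavalieri method with Monte Carlo permutation tests and FDR control,
    build probabilistic maps and maximum probability maps from co-registered
    subject label volumes (centre of gravity, 3D map correlation,
    coordinate-to-area assignment), and quantify inter-areal similarity via
    Euclidean feature distances, metric multidimensional scaling and UPGMA
    clustering with Newick export. A synthetic-data generator provides
    laminar ribbons, GLI images and multi-subject label volumes with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    ape,
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
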