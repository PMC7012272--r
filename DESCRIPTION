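Package: triplanar
Title: Tri-Planar Multichannel 2D Convolutional Networks for Task fMRI
    Volume Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classify task-evoked 3D fMRI volumes with a multichannel 2D
    convolutional network that slices each brain volume along the three
    anatomical axes and learns the three slice stacks in parallel (M2D CNN),
    together with five comparison models (single-plane 2D, mean-value 2D,
    1D, 3D, and 3D separable-convolution networks, and a PCA+SVM baseline).
    Includes block-design preprocessing (fixation baseline and mean percent
    signal change), per-voxel normalization, closed-form flatten-unit and
    parameter accounting for every architecture, a subject-wise k-fold
    cross-validated training and evaluation harness with Adam, a stepped
    learning-rate schedule and train-loss early stopping, and a synthetic
    motor-task generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
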