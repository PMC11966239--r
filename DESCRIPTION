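Package: cryofield
Title: Cryo-EM Density Reconstruction with Multi-Resolution Hash Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gradient-based single-particle cryo-EM density-map
    reconstruction with known pose and contrast transfer function (CTF).
    A trainable scalar field (multi-resolution hash grid with a small MLP
    decoder, with voxel and frequency-encoded baselines) is queried at
    pose-rotated, jittered 3D grid points, projected to the image plane by
    a fixed sparse operator and corrupted by the CTF, and is optimized
    end-to-end under Gaussian white-noise losses (mean-squared error,
    scale-invariant cross-correlation, and a marginalized likelihood with
    a Gaussian prior on global scale and offset). Conformational
    heterogeneity is modelled by bending the query coordinates with a
    per-image vector field inferred by an amortized encoder. Includes a
    synthetic-data simulator (Gaussian-mixture bead densities, uniform
    poses, realistic CTFs, white noise), Fourier shell correlation and
    classification metrics for validation, MRC/MRCS and STAR (RELION
    dialect) readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    kernlab,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
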