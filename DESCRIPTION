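Package: eccentric
Title: Eccentric-Circle k-Space Trajectories and Low-Rank Reconstruction for
    Spatial-Spectral MRSI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of random eccentric-circle k-space sampling trajectories
    for spatial-spectral magnetic resonance spectroscopic imaging (MRSI),
    together with rosette, concentric-ring and uniform-circle comparators,
    point-spread-function and gradient-demand analysis, a digital
    Derenzo-style structural-metabolic phantom with a coil-wise (k,t)
    forward encoder, spectral preprocessing (HSVD water removal, field-map
    and coil-sensitivity estimation, backward linear prediction), and a
    compressed-sensing SENSE low-rank reconstruction with second-order
    total-generalized-variation regularization and lipid-subspace
    suppression. Includes evaluation metrics (SSIM, correlation, spectral
    SNR and linewidth, coefficients of variation) and a linear-combination
    spectral quantification into metabolite maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
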