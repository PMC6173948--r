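Package: fcmvalid
Title: Unsupervised Fuzzy C-Means Clustering of Time-Course Data with
    Cluster Validity Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fuzzy c-means clustering of voxel time-courses (e.g., fMRI)
    using a square-root-modified hyperbolic correlation distance, together
    with the full family of fuzzy compactness and separation measures and
    eight cluster validity indices (Rezaee-Lelieveldt-Reider,
    Zahid-Limouri-Essaid, Geva, Kim-Park, Pakhira-Bandyopadhyay-Maulik,
    Wu-Yang, Bouguessa-Wang-Sun, and a compactness-separation product
    index) for unsupervised selection of the number of clusters. Includes
    an automated sweep over candidate cluster counts with multi-restart
    initialisation, a synthetic benchmark generator with ground-truth
    labels, morphological granulometry of crisp 3D cluster maps, and NIfTI
    input support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
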