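Package: gmprog
Title: Progressive Grey-Matter Atrophy Analysis on the Cortical Skeleton
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for longitudinal voxel-based morphometry of grey-matter
    volume (GMV) sampled on the cortical skeleton. Provides a synthetic
    longitudinal cohort generator with planted atrophy, covariance and
    brain-behaviour structure; skeletonization of a cohort-mean GM map by
    Hessian ridge detection; voxelwise two-sample and paired t maps with
    Benjamini-Hochberg FDR correction and 26-connectivity cluster
    filtering; derivation of overlapped, continuing and progressive
    atrophy regions; ROI mean-GMV extraction, change scores and
    brain-behaviour correlation; structural covariance network edges with
    permutation group-difference tests and cross-lagged (Granger-style)
    causal covariance effects with subject bootstrap; and linear-SVM
    discrimination of patient groups under leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
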