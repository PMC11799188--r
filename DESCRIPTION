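Package: tcgrad
Title: Thalamocortical Connectivity Gradients and Spatially
    Autocorrelated Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Derives low-dimensional axes ("gradients") of thalamocortical
    connectivity from seed-voxel-by-cortical-parcel matrices using a
    normalized-angle affinity kernel and diffusion map embedding.  Builds
    the three connectivity modalities around the embedding: streamline-count
    structural connectivity (group averaging, column-max normalization,
    percentile thresholding), functional connectivity (Pearson correlation
    of time series with row-wise Fisher z transform), and across-subject
    structural covariance of quantitative T1.  Gradients are contextualized
    against intrathalamic scalar maps with variogram-matched surrogate maps
    that preserve spatial autocorrelation, projected onto the cortex by
    column-wise correlation, and decoded against nucleus and functional
    community parcellations.  A synthetic-data generator plants two latent
    thalamic axes in all modalities so the full pipeline is testable without
    MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
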