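Package: connparc
Title: Connectivity-Based Parcellation and Network Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for connectivity-based parcellation of
    small gray-matter regions from resting-state fMRI, built around the human
    olfactory amygdala (medial amygdala, cortical amygdala, periamygdaloid
    complex). Provides template-space time-series cleaning (volume dropping,
    polynomial detrending, nuisance regression, grand-mean scaling, Fourier
    band-pass, Gaussian smoothing), voxel-to-whole-brain Pearson connectivity
    profiles with Fisher-z group averaging, correlation-distance k-means
    parcellation, permutation tests with normal-fit z-scores for parcellation
    accuracy, seed-based connectivity maps with threshold-free cluster
    enhancement (TFCE) and sign-flip family-wise error correction, and the
    partition of subregion networks into unique, pairwise-shared and all-shared
    categories with Venn voxel counts. A seeded multi-subject BOLD phantom with
    planted subregion-network structure makes every stage verifiable without
    access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
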