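Package: voxelFD
Title: Per-Region 3D Box-Counting Fractal Dimension for Segmented Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the Minkowski-Bouligand (box-counting) fractal
    dimension of three-dimensional regions in segmented brain MRI label
    volumes. Provides a logarithmically spaced box-edge schedule,
    origin-anchored box counting at non-integer scales, a log-log
    least-squares fit with a root-mean-square-error linearity diagnostic,
    synthetic fractal phantoms of known dimension (Menger sponge, Euclidean
    solids, random blobs), per-region morphometry with multi-session
    comparison tables, Clinical Dementia Rating based cross-sectional cohort
    labeling, and cross-validated support vector machine classification of
    regional (volume, fractal dimension) features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
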