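Package: cueReg
Title: Visual-Cue Based Adaptive Registration of Time-Lapse Microfluidics Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-free rigid registration of time-lapse phase-contrast
    image series from microfluidics experiments. Structural "visual cue"
    polygons (chamber spacers) are detected in each frame by a preprocessing
    pipeline (bilateral denoising, contrast-limited adaptive histogram
    equalization, adaptive mean thresholding, dilation, border clearing and
    circular masking), filtered by their perimeter-to-area ratio, and reduced
    to three control points per frame from which pairwise affine transforms
    are estimated and chained to the first frame. Includes a synthetic scene
    generator with ground-truth drift trajectories, evaluation metrics
    (cue-position root mean square difference and image closeness), and a
    probabilistic Hough transform baseline for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
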