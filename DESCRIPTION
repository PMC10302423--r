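Package: solscreen
Title: Automated Visual Solubility Screening from Paired Flask Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the dissolution state of a solution (dissolved,
    cloudy-undissolved, particulate-undissolved) from two photographs of a
    flask taken over a tablet showing a plain white and a checked background.
    Nine handcrafted vision features are extracted per sample: grid
    homogeneity statistics (MMG, MSG, SMG, SSG), radial-profile quadratic-fit
    descriptors (minimum value, curvature, MSE), an undissolved-particle
    pixel count from adaptive thresholding plus Gabor filtering, and a
    check-pattern superposition ratio. Features feed a small dense neural
    network or a linear support vector machine. Includes a parametric
    synthetic flask-scene generator with pixel-level ground truth, a circle
    Hough transform region-of-interest detector, a Moire-suppression stage
    (contrast stretch plus non-local means), evaluation utilities
    (stratified k-fold cross-validation, confusion matrices, TPR/PPV), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
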