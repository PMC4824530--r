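Package: hpft
Title: Homographic Patch Feature Transform for Endoscopic Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based registration of endoscopic-style image pairs and
    sequences under the assumption that a smooth internal organ surface is
    composed of many small homographic (locally planar) patches. Detects
    interest points with a simplified 32-element SIFT descriptor, estimates
    the epipolar constraint, clusters matches into Delaunay triangle patches,
    validates each patch's affine homography by normalized cross-correlation,
    and iteratively splits failed patches at their incircle centers, matching
    the centers along epipolar segments until a fixpoint. Ships a seeded
    synthetic-scene generator with exact ground-truth warps, lens
    undistortion and specular-highlight masking, and the full evaluation
    scheme: forward-backward tracking error, precision percent validation,
    Kullback-Leibler trajectory divergence, covariance-based robustness under
    injected noise, and coordinate-uniformity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    interp,
    Rcpp,
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
LinkingTo:
    Rcpp
Config/testthat/edition: 3
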