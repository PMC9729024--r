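Package: birddog
Title: Video-Based Postural Control Indices for the Bird-Dog Balance Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying postural control from markerless 2-D body
    keypoint trajectories of the bird-dog (one-arm-one-leg) balance task.
    Denoises pose-estimator output (visibility thresholding, iterated
    exponentially weighted moving outlier rejection, linear interpolation),
    computes three static postural balance indices (SPB1-SPB3, based on
    trunk-normalised keypoint displacement and convex-hull excursion area)
    and three antigravity indices (AG1-AG3, based on limb segment angles),
    and relates the indices to clinician ratings via ordinary least squares
    and backward stepwise AIC model selection.  Includes a synthetic trial
    and cohort generator with known ground truth and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
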