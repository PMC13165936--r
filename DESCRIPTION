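Package: pupilkit
Title: Webcam Pupillometry from Markerless Keypoint Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for webcam-based video pupillometry.
    Converts markerless pose-estimation keypoint tracks (eight pupil-boundary
    points plus a skin-mounted reference marker of known physical size) into
    calibrated pupil-diameter time series in millimetres. Includes robust
    two-stage conic/ellipse fitting with distance-based outlier rejection,
    temporal cleaning of keypoint and area series (sliding-median smoothing,
    asymmetric IQR gating, gap-limited linear interpolation), reference-length
    scale normalisation, non-parametric Bland-Altman agreement analysis,
    exact Wilcoxon signed-rank tests, nociceptive pupillary-response
    quantification, and a synthetic keypoint-session generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
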