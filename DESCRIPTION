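Package: feedkin
Title: Feeding Kinematics of Young Broiler Chicks from High-Speed Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-free analysis of broiler chick feeding kinematics from
    lateral high-speed frame sequences. Provides a synthetic feeding-scene
    generator with exact ground truth (eye, beak wedges, feed particles,
    calibration ruler), a machine-vision pipeline (eye detection, head-region
    extraction, feed-particle pixel removal, beak-tip detection, ruler
    calibration), segmentation of the beak-gape series into mandibulation
    cycles with temporal ordering and catch-and-throw flagging, the four
    kinematic variables (maximum beak gape, head displacement, duration,
    average head speed), a nonparametric statistical battery (Spearman rank
    correlation, Mood's median test, chi-square frequency test, descriptive
    summaries), and sieve-based feed granulometry (geometric mean diameter
    and geometric standard deviation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
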