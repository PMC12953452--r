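Package: rowcountr
Title: Row-Based Seedling Counting from Detection Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting crop seedlings in a planted row from per-frame
    object-detector output of an oblique-view walking video. Implements
    density-adaptive DBSCAN clustering that eliminates detections from
    neighbouring rows and ditch clutter under perspective distortion, a
    SORT-style multi-object tracker (constant-velocity Kalman filter,
    Hungarian assignment on intersection-over-union) with permanent-ID
    retirement when a track crosses the lower frame edge, the detection,
    tracking and counting evaluation metrics used in field phenotyping, and a
    pinhole-camera scene simulator that generates perspective-distorted
    detection streams with full ground truth so the whole pipeline can be
    exercised without video data or a trained detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
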