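Package: flockzone
Title: Robot-Induced Spatial Redistribution of Broiler Flocks from
    Overhead Detection Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how an autonomous ground robot changes the spatial
    distribution of broiler chickens from per-frame object-detection tables.
    Reconstructs the robot trajectory from detected centroids, buffers it
    into a zone of influence, counts birds whose centroids fall inside the
    zone at 1-s resolution, expresses counts as relative density against a
    pre-entry baseline, summarises the moment-prior / one-minute / two-minute
    time points, and fits linear repopulation models with extrapolated full
    repopulation times. Also implements detection-performance evaluation
    (IoU matching, precision, recall, F1, mAP), simple ethogram statistics
    (occurrence proportion tests, rank transforms), and an agent-based
    synthetic-flock simulator with flee-and-return dynamics and detection
    noise so that every stage of the pipeline can be tested without farm
    video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
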