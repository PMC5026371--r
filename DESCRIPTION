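Package: pawtrackr
Title: Color-Based Forepaw Tracking and Grooming Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless video-tracking engine for individual mouse forepaws
    labelled with neon colors, built on HSV color masking, hue-histogram back
    projection and mean-shift clustering with adaptive windows and loss
    recovery, for one, two or four mice in divided behavioral arenas.
    Downstream analytics quantify forepaw kinematics (speed, path length,
    covered area, occupancy maps, inter-paw distance, bilateral lag and
    correlation) and classify grooming versus walking bouts, including
    episode detection. A deterministic synthetic-scene renderer produces test
    videos with exact ground-truth trajectories.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    EBImage,
    png,
    tiff,
    xml2,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
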