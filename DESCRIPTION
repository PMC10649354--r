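Package: grazetrack
Title: GPS Collar Trajectory Analysis for Cattle Grazing Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to ingest, clean, and geofence second-by-second GPS
    collar fixes from grazing cattle; compute daily distance traveled and
    rate of travel; classify resting, grazing, and traveling time from
    movement speed; quantify zone occupancy, landscape preference
    indices, and kernel-density hotspots; compute the
    temperature-humidity index from climate records; summarize
    randomized complete block grazing trials with a fixed-effects
    analysis of variance; and simulate collar datasets with known ground
    truth from a correlated-random-walk herd model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
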