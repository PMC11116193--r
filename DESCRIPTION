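Package: ibisflight
Title: Heart-Rate, Body-Acceleration and Migration-Distance Pipelines for
    Bird Biologging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Processing pipelines for animal-borne sensor data from flying
    birds: QRS detection and density-filtered heart-rate extraction from
    raw electrocardiogram traces, vectorial dynamic body acceleration
    (VeDBA) from tri-axial accelerometry, flapping/gliding flight
    segmentation from the dynamic heave axis, daily flight-distance and
    migration/stopover classification from GPS tracks, and the associated
    linear and random-intercept mixed models (REML fitted from first
    principles).  Includes synthetic-data generators for ECG,
    acceleration and GPS itineraries with known ground truth, so every
    stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
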