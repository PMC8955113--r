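Package: thermofall
Title: Activity Scoring and Fall Detection from Low-Resolution Thermal
    Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-invasive monitoring of older adults from low-resolution
    infrared sensor streams (32x24 thermopile arrays and 8-pixel line
    sensors). Implements weighted-moving-average background subtraction
    and hourly/monthly activity scoring, a lossless trailing-zero record
    codec with capture-validity rules, and a fall detector that binarizes
    frames, thins them to single-pixel skeletons (Zhang-Suen), converts
    skeletons to spatiotemporal graphs, embeds the graphs with
    Weisfeiler-Lehman subtree features trained PV-DBOW style (Graph2Vec),
    and classifies fall versus non-fall windows with a random forest.
    Includes a synthetic thermal-scene simulator for generating labeled
    activity and fall sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
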