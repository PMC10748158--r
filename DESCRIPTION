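Package: BusProximity
Title: Social Distancing Analysis on Public Transport from Ceiling-Mounted
    Depth Cameras
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for approximating social distancing on a bus from a single
    ceiling-mounted RGB-D camera. Per-passenger pose keypoints and 16-bit depth
    frames are deprojected through the pinhole camera model to metric 3D nose
    positions; pairwise nose-to-nose distances are binned into epidemiological
    risk bands (<1 m, 1-2 m, >2 m) and summarised per occupancy level as inputs
    for quantitative microbial risk assessment. A robust least-median-of-squares
    homography maps passengers onto a labelled bus floor plan for seat-level
    occupancy time series. A ground-truthed synthetic bus-scene generator
    (Poisson boarding/alighting, rendered depth frames, COCO-style keypoints)
    supports fully offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    digest,
    pracma,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'intrinsics.R'
    'seatplan.R'
    'scenario.R'
    'simulate.R'
    'frame-io.R'
    'preprocess.R'
    'geometry.R'
    'proximity.R'
    'seatmap.R'
    'reporting.R'
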