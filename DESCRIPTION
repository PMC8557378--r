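Package: whorltls
Title: Whorl-Level Branch Attributes and Biomass of Conifers from
    Terrestrial Laser Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates whorl-level and individual-branch attributes
    (branch number, basal area, diameter and dry biomass) of conifer
    trees by bridging terrestrial-laser-scanning-derived stem geometry
    with pipe-model-based tree structure models. Builds a spline-based
    stem taper curve from slice diameters, clusters trunk-attached
    branch detections into whorls with gap-filling in the occluded
    upper crown, allocates whorl basal area by pipe model theory,
    samples individual branch sizes under relative-extreme constraints,
    and converts diameters to dry mass with a log-linear branch biomass
    model. Includes TLS-based comparison estimators (cylinder volume
    times wood density, stump-diameter allometry, crown-base pipe-model
    allometry), a full detection and agreement evaluation suite
    (commission and omission errors, RMSE, CV-RMSE, Lin's concordance
    correlation, Kolmogorov-Smirnov ECDF comparison by crown layer),
    and a synthetic-tree simulator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
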