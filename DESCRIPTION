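Package: cottoncanopy
Title: Canopy Height and Leaf Area Index Estimation from UAV Photogrammetry Point Clouds
Version: 0.1.0
Authors@R:
    person("Field", "Phenomics Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates cotton canopy height and leaf area index (LAI) from
    georeferenced dense point clouds such as those produced by UAV
    structure-from-motion photogrammetry. Provides local tangent-plane
    (east-north-up) geodetic transforms from WGS84 through ECEF,
    orthogonal-distance terrain plane fitting, sample-based ground-elevation
    inversion, digital surface model rasterization with percentile canopy
    upper boundaries, canopy point-density occupancy statistics, canopy
    diameter extraction, and a multivariate linear LAI model fitted by
    stepwise least squares. Includes a synthetic cotton-field point-cloud
    generator with full ground truth so the entire pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
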