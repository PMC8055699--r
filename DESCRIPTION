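Package: irissmooth
Title: Automated Smoothness Index of the Anterior Iris Border in AS-OCT Images
Version: 0.1.0
Authors@R:
    person("Farabi", "Imaging Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the smoothness index (SI) of the anterior iris border in
    anterior-segment OCT B-scans: preprocessing (crop, histogram matching,
    intensity complement), adaptive K-means binarization, morphological
    cleanup, border extraction, geodesic (along-border) and chord length
    measurement between operator-selected landmarks, and the SI ratio.
    Includes a synthetic AS-OCT iris phantom generator with analytically
    known SI for validation, method-agreement statistics (Bland-Altman
    limits of agreement, two-way random ICC, inter-eye differences), and a
    scriptable command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
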