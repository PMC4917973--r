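Package: fishHeadTracker
Title: Multiple Fish Tracking in Top-View Video by Head Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and tracks multiple swimming fish in top-view grayscale
    video. Fish are detected by extracting the centerline of each moving
    region with an augmented fast marching skeletonization, locating head
    endpoints by branch-length and inscribed-circle width thresholds, and
    estimating head direction from the eigenvectors of a multiscale Hessian.
    Detections are linked across frames by a gated position-and-direction
    cost minimized with the Hungarian algorithm, keeping the population size
    fixed through occlusions by propagating unmatched tracks. Includes a
    ground-truthed synthetic swimming-fish generator and the standard
    detection and tracking evaluation criteria (ACDR, AEDR, AODR, ADE,
    MTT, PTT, TIS).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
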