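Package: cortexCT
Title: Cortical Bone Profiling of Murine Metatarsals from Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of arthritic cortical-bone
    degradation in murine metatarsals from micro-computed tomography
    image stacks. Segments bone from soft tissue with a Gabor and
    difference-of-Gaussians filter bank followed by two-cluster
    k-means++ pixel clustering, isolates single metatarsals by tracking
    connected regions across slices from a manual seed, resamples
    cross-sections locally orthogonal to the bone axis so that
    measurements are independent of specimen placement in the scanner,
    and measures the cortical thickness profile. Summarises each bone
    by the cortical thickness gradient (CTG, the slope of angularly
    averaged cortical thickness along the bone) and the average
    cortical thickness index (CTI). Includes a synthetic tubular-bone
    phantom generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
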