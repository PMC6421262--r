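Package: ectoloc
Title: Noninvasive Localization of Ectopic Cardiac Activation Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing the origin of a focal (ectopic or paced)
    ventricular activation from body surface potential maps (BSPMs). For
    every node of a triangulated heart surface a candidate activation
    sequence is simulated with a fastest-route (graph shortest-path)
    propagation model, mapped to torso electrode potentials through an
    equivalent-dipole-layer forward model, and ranked against a measured
    or reference BSPM either by correlation or by reciprocal dynamic
    time warping (DTW) distance. The time-warping step compensates for
    local conduction-velocity disturbances that violate the global-CV
    assumption of the fastest-route model. Includes synthetic heart and
    torso geometry generators, mesh I/O (OFF, PLY, VTK legacy), a
    boundary-element bounded-conductor correction, localization-error
    metrics, BCa bootstrap confidence intervals, Wilcoxon signed-rank
    comparison, and a multi-scenario evaluation battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
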