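Package: leverlog
Title: Analysis of Adaptive Home-Cage Lever-Pulling Behavior in Group-Housed Mice
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated home-cage motor phenotyping with an adaptive
    lever-holding task. Implements the task logic (trial classification and the
    daily 75th-percentile hold-time scheduler), an exponential-Gaussian mixture
    model of hold-time distributions with per-day maximum-likelihood fits,
    movement-jerkiness quantification by zero-phase 10 Hz high-pass filtering,
    trial-to-trial variability analyses built on dynamic time warping and
    moving standard deviations, chamber-entry engagement and bout-size metrics,
    and detection of follower-influencer social motifs in multi-animal event
    logs. A closed-loop agent-based cage simulator generates wild-type-like and
    disease-model-like synthetic session logs so that every analysis stage can
    be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
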