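Package: cpforage
Title: Age and Environment Effects on Central-Place Seabird Foraging
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse GPS tracking data from central-place foraging
    seabirds: regularisation and daylight annotation of fix series,
    delimitation of foraging absences, four-state behavioural annotation from
    speed and turning angle, per-absence foraging traits (absence duration,
    total distance, time searching, mass gain, mass gain rate), two-stage
    linear mixed-model selection of piecewise threshold and quadratic age
    functions with AICc and age-by-environment interactions, and kernel
    utilization-distribution overlap (Bhattacharyya affinity) with
    track-level randomization tests and false-discovery-rate control. A
    synthetic central-place-forager generator with known ground truth
    supports validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS
Config/testthat/edition: 3
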