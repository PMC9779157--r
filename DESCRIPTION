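Package: preevac
Title: Pre-Evacuation Decision-Timing Models for Crowds in Emergencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time survival models for the pre-evacuation phase of
    crowd emergencies. Each pedestrian faces a per-period probit hazard of
    switching from a wait-and-see state to immediate escape, driven by
    personal risk tolerance (age, gender, education, familiarity, group
    size, residence distance, travel mode), the standardized strength of the
    hazard event, distance from the danger source, and the reaction of the
    surrounding crowd. The package provides the escape-selection threshold
    model and its first-passage likelihood, maximum-likelihood calibration
    with a natural-response (control-group) correction, a synthetic survey
    generator for parameter-recovery studies, and an agent-based multi-zone
    fire-scene simulator with a linearly spreading smoke front.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
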