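Package: stickwalk
Title: Neuromechanical Simulation of Six-Legged Stick-Insect Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kinematic neuromechanical model of stick-insect walking. Six legs,
    each with three antagonistic muscle pairs, are driven by a network of
    central-pattern-generator (CPG) half-center oscillators, inhibitory premotor
    interneurons and fast/slow motoneurons (216 model neurons, 648 first-order
    ODEs) coupled to second-order joint dynamics (18 ODEs). Sensory signals from
    the leg joints gate the intraleg networks and the ipsilateral and
    contralateral coordination pathways. The package simulates walking-related
    behavioural modes (tripod and tetrapod gaits and transitions, stop and
    restart, front-leg search movements, backward walking, combined schedules)
    and provides a gait-diagram toolkit: swing/stance extraction,
    coordination-pattern classification, irregularity detection and
    transition-start scan experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
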