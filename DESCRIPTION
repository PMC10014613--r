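Package: cpgwalk
Title: Forward-Dynamics Simulation of Bipedal Gait with a CPG Controller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional neuromusculoskeletal walking simulator: a
    seven-segment planar skeleton (head-arms-trunk, thighs, shanks, feet)
    actuated by 18 Hill-type muscles and driven by a Matsuoka-style central
    pattern generator with sensory feedback and posture reflexes. Controller
    parameters are found by a generational genetic algorithm maximising
    walking distance and metabolic economy. Includes a unilateral transtibial
    amputation/prosthesis manipulation, gait event detection, spatiotemporal
    gait parameters, metabolic cost of transport, and gait symmetry indices,
    so normal and amputee (symmetric- vs asymmetric-feedback) control
    scenarios can be simulated and compared.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
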