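Package: synprime
Title: Sequential Two-Step Vesicle Priming Models of Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and fits a sequential two-step synaptic vesicle
    priming-and-fusion model with four docking states (empty, loosely
    docked, tightly docked, and a labile tightly docked state) and
    calcium-dependent priming rates. Includes the stimulation protocols
    used in paired pyramidal-cell/interneuron recordings, joint
    multi-protocol root-mean-square-deviation fitting with parameter-subset
    ladders and shared-scaling-factor fits, pharmacology scenario
    constraints, quantal short-term plasticity metrics, and a synthetic
    paired-recording data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
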