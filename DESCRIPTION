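Package: thrombosim
Title: Coupled Pharmacokinetic-Pharmacodynamic Simulation of Intravenous
    Thrombolysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulator of intravenous thrombolytic therapy for
    acute ischemic stroke. Couples a two-compartment systemic
    pharmacokinetic-pharmacodynamic model of the plasma fibrinolytic
    system (plasminogen activation, PAI-1 inhibition, plasmin inhibition
    by alpha2-antiplasmin and alpha2-macroglobulin, fibrinogenolysis)
    with a one-dimensional porous-medium model of an occluding fibrin
    clot: Darcy flow through the fibre network, convection-diffusion-
    reaction transport of the fibrinolytic proteins, adsorption to fibrin
    binding sites, bound-phase Michaelis-Menten plasmin generation, and
    plasmin-mediated binding-site degradation. Ships dose-regimen and
    kinetic-parameter presets for alteplase, tenecteplase, reteplase and
    urokinase, and computes efficacy and safety read-outs (clot lysis
    time, activation time, drug exposure, fibrinogen depletion, PAI-1
    resistance) for cross-drug comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
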