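Package: rearmech
Title: Mechanochemical ODE Model of Cell Rear Retraction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction, compilation and deterministic simulation of a
    mass-action ordinary differential equation model of rear retraction in
    matrix-directed cell migration. A declarative wiring diagram of the
    caveolae-RhoA-actomyosin signalling axis is expanded into elementary
    mass-action reactions under explicit formulation rules (two-step
    protein-protein binding/conversion, one-step biophysical state changes,
    bounded reversibility, first-order turnover), integrated with an
    LSODA-style stiff solver, and interrogated through a catalogue of
    in-silico perturbation scenarios (knockdowns, substrate transitions,
    osmotic shock, kinase inhibition, actin depolymerisation), scaled
    parameter sensitivity analysis, halve/double robustness sweeps, and
    seeded parameter-ensemble classification. Models export to and import
    from SBML Level 3.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
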