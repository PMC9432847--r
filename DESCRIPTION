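Package: retmicro
Title: Hybrid Hemodynamic and Oxygen Transport Model of the Retinal Microcirculation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood flow, oxygen transport, and conducted metabolic
    signaling in a hybrid model of the retinal microcirculation. A
    heterogeneous arteriolar tree is solved for Poiseuille flow with
    diameter- and hematocrit-dependent apparent viscosity and red-cell phase
    separation at bifurcations, and for coupled intravascular-tissue oxygen
    transport by a Green's function method. Every terminal arteriole feeds a
    series chain of capillary, small-venule, and large-venule compartments;
    capillary oxygen extraction follows a Krogh cylinder model with
    Michaelis-Menten consumption kinetics. A conducted metabolic wall signal,
    inversely related to local oxygen tension, is propagated upstream from the
    venules through the arteriolar network. Includes a seeded synthetic
    vascular tree generator, CSV/JSON network I/O, and a demand-sweep driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
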