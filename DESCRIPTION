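Package: pbpkbe
Title: Physiologically Based Pharmacokinetic Modelling and Virtual
    Bioequivalence for Oral Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mechanistic oral-absorption and disposition modelling for
    comparing oral dosage forms of the same drug. Implements pH-dependent
    solubility of diprotic acids, diffusion-layer particle dissolution with
    closed-vessel USP II simulation, a catenary gastrointestinal
    transit-and-absorption model, a minimal physiologically based
    pharmacokinetic (PBPK) disposition model with mechanistic volume of
    distribution and retrograde intrinsic clearance, noncompartmental
    analysis, virtual-population generation, crossover and parallel virtual
    bioequivalence trials with geometric mean ratio statistics, physiology
    sensitivity analysis, and biopharmaceutical safe-space mapping. Ships a
    complete parameterisation for bempedoic acid 180 mg oral suspension
    (test) versus immediate-release tablet (reference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
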