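Package: deglypk
Title: Mechanism-Based Parent-Metabolite Pharmacokinetics of Ginsenoside Rh2 Deglycosylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compartmental pharmacokinetic modelling of the deglycosylation of
    20(S)-ginsenoside Rh2 to its aglycone protopanaxadiol (PPD) in the rat.
    Implements the eleven-compartment parent-metabolite model (plasma and
    peripheral compartments for both analytes, a stomach compartment with
    acid-hydrolysis loss, an intestinal transit chain feeding a colonic
    compartment where gut microbiota deglycosylate Rh2, and biliary excretion
    of Rh2 into the gut), exact linear-system simulation, staged sub-model
    parameter estimation with a naive-pooled proportional-error likelihood,
    closed-form elimination-route accounting with an independent flux-integration
    oracle, non-compartmental analysis, visual predictive checks, and a
    synthetic rat-study generator matching the original crossover design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
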