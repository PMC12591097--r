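Package: icldepot
Title: Mechanistic Pharmacokinetics of Intramuscular Long-Acting Injectable
    Depots with an Inflammatory Cell Layer Barrier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates plasma concentration-time profiles after intramuscular
    administration of long-acting injectable (LAI) suspensions, solutions and
    intravenous infusions. The depot model combines polydisperse Johnson-type
    particle dissolution, a time-varying inflammatory cell layer (ICL)
    diffusion barrier around the depot, perfusion/partition-limited drug
    egress, and linear three-compartment systemic disposition with
    instantaneous prodrug cleavage. Includes non-compartmental metrics and
    fold-error validation, bounded least-squares calibration of the ICL
    kinetics against observed pharmacokinetic data, one-at-a-time parameter
    sensitivity sweeps, and a synthetic-profile generator for parameter
    recovery studies. Ships ready-made scenarios for aripiprazole lauroxil
    (Aristada) suspensions and aripiprazole solution/infusion dosing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
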