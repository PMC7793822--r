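Package: vicapkpd
Title: Physiologically Based Pharmacokinetic/Pharmacodynamic Simulation of
    Vicagrel and Clopidogrel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minimal physiologically based pharmacokinetic (PBPK) models of the
    antiplatelet prodrugs vicagrel and clopidogrel, covering their sequential
    two-step activation to the common active thiol metabolite AM-H4, linked to
    an irreversible-inactivation turnover model of platelet aggregation.
    Includes virtual-population sampling with log-normal inter-individual
    variability, CYP2C19 phenotype and carboxylesterase (CES1/CES2) genotype
    scenarios, reversible and mechanism-based enzyme-inhibition drug-drug
    interaction simulation (simvastatin, omeprazole), non-compartmental
    summaries, and a synthetic observed-data generator for fold-error
    verification workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
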