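Package: dtikin
Title: Quantitative Pharmacology of Direct Thrombin Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for the quantitative characterisation of
    direct thrombin inhibitors (DTIs): tight-binding enzyme-inhibition
    kinetics with the Morrison equation, competitive-mode Ki from the
    substrate dependence of the apparent inhibition constant, logistic
    IC50 fits, serine-protease selectivity panels, clot-waveform and
    thrombin-generation trace analysis with log-log intensity gradients,
    censored RT50 dose-response and therapeutic-index estimation from
    rodent thrombosis/bleeding models, and 1:1 biolayer-interferometry
    binding kinetics. Ships seeded synthetic-data generators for every
    assay read-out so the full pipeline is testable without instrument
    data, plus a transcribed table of peptide sequences and inhibition
    constants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
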