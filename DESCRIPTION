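Package: fusafferent
Title: Dose-Response Analysis of Focused-Ultrasound-Evoked Activity in
    Peripheral Sensory Afferents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for teased-fiber extracellular recordings of
    peripheral sensory afferents stimulated with focused ultrasound (FUS),
    electrical pulses, and mechanical probes. Provides template-correlation
    spike sorting with the five classical waveform features,
    conduction-velocity-based afferent classification (Abeta RA/SA, D-hair,
    AM, C), per-fiber action-potential probability tables, sonication-energy
    transforms, logistic dose-response fits (Max_AP, EC50, E50-probability),
    activation-threshold estimation at receptive fields and nerve trunks,
    FUS-versus-electrical latency analysis, genotype-level cumulative
    response profiles, exact nonparametric tests, and a seeded synthetic
    recording generator so that every stage of the pipeline is testable
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
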