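Package: efpnf
Title: Simulation and Analysis of EEG Fingerprint Amygdala Neurofeedback Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating single-channel EEG "electrical
    fingerprint" (EFP) models of amygdala BOLD activity and for simulating and
    analysing closed-loop neurofeedback trials that use them. Includes a
    Stockwell-transform time-frequency feature pipeline with energy-uniform
    frequency banding and ridge-regression model fitting; a closed-loop
    Watch/Regulate session engine with z-scored 1-10 feedback and regulation
    success indices; a synthetic-data layer (latent arousal processes, coupled
    EEG and BOLD, learning agents, clinical cohorts) so that every stage is
    testable without access to recordings; single-ROI fMRI GLM contrasts with
    canonical double-gamma HRF regressors; and the trial-level inferential
    toolkit (ANCOVA, REML mixed models with compound symmetry,
    repeated-measures ANOVA, learning contrasts, FDR, absolute risk reduction
    and number needed to treat). BrainVision, CSV, JSON and YAML adapters and a
    small command-line front end tie the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
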