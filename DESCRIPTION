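Package: rtbold
Title: Trial-by-Trial RT-BOLD Regression and RT-Equated Congruency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Event-related fMRI analysis of the relationship between
    reaction time (RT) and the BOLD response, built around RT-equated
    congruency contrasts for response-interference tasks. Provides a
    synthetic multi-subject generator for a multi-source interference
    task (MSIT) plus a simple RT task under two competing generative
    accounts of the congruency effect (time on task versus conflict
    monitoring), first-level general linear models with mean-centered
    parametric RT modulators, motion and discrete-cosine drift nuisance
    blocks and AR(1) prewhitening, RT-equated congruent-activity
    estimates from within-condition RT-BOLD slopes, and random-effects
    group inference with FDR control, cluster-extent filtering,
    conjunction masks and sphere ROI summaries.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
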