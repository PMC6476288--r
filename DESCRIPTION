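Package: copegrow
Title: Individual Growth Trajectories of Copepods Under Multiple Stressors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of high-temporal-resolution individual growth data from
    automated well-plate imaging of copepods. Provides a stage-structured
    simulator of the observation process (hourly frames, stage-dependent
    detection dropout, unusable-frame episodes, machine measurement bias),
    per-individual penalized-spline growth smoothers with isochronal
    predictions and growth increments, moult detection from increment peaks
    including the naupliar-to-copepodite metamorphosis with its
    uncertain-frame and motion-free accounting, and uncertainty-weighted
    linear models with AICc-based selection and conditional model averaging
    for effects of a toxicant (copper) and predator cues on stage-transition
    timing, moult duration and final body size, plus hierarchical GAMs for
    growth dynamics and a machine-versus-manual length calibration model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mgcv,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
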