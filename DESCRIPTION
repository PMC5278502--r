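Package: circaquant
Title: Single-Cell Fluorescence Circadian Rhythm Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of circadian clock-reporter dynamics from
    time-lapse fluorescence imaging of single neurons. Provides ROI and
    3D-mask intensity extraction with background correction, trace
    normalization and heatmap construction, maximum entropy spectral
    analysis (tapered Burg autoregressive estimation) for circadian
    period estimation from short noisy time series, a dual-criterion
    (polynomial-trend plus spectral) rhythmicity classifier, two-way
    ANOVA with Sidak-corrected per-timepoint comparisons for
    drug-response time courses, and seeded synthetic-data generators
    (traces, cohorts, pharmacology experiments, 3D image stacks) with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    car,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
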