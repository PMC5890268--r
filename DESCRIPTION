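Package: catenaflux
Title: Drought-Period Greenhouse Gas Flux Analysis for Topographic Catenas
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing soil greenhouse-gas dynamics across
    ridge-slope-valley catenas through drought events: closed-chamber CO2
    and CH4 flux estimation with linear and exponential concentration
    models and quality control; piecewise-linear segmentation of soil
    moisture records with BIC breakpoint selection and a supF
    structural-change test; drought-period by topographic-zone summaries,
    repeated-measures ANOVA and hot-moment detection; and Monte Carlo
    upscaling of cumulative CO2-equivalent emissions using topographic
    weighting and global-warming-potential conversion. A synthetic catena
    data generator with known ground truth makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
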