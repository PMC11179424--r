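Package: RepeatInstability
Title: Somatic CAG-Repeat Instability from Capillary Fragment Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies somatic expansion of the HTT CAG repeat from
    capillary-electrophoresis fragment analysis. Converts peak tables or raw
    electropherogram traces to repeat-length distributions via ladder sizing
    and a calibrated linear size-to-repeat map, applies modal-height
    thresholding, and computes the modal repeat and a modified instability
    index. Estimates per-condition expansion rates over time-course designs
    with replicate cultures (two-stage replicate-slope estimator with a
    mixed-model alternative), percent slowing relative to a non-targeting
    control, and Tukey-adjusted pairwise contrasts. Includes a seeded
    generative simulator of repeat-length populations (length-dependent
    Poisson gain/loss walk), PCR stutter, and synthetic traces, so the whole
    pipeline is testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RepeatInstability-package.R'
    'pipeline.R'
    'repeat-metrics.R'
    'sim-expansion.R'
    'timecourse-stats.R'
    'trace-io.R'
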