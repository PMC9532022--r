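Package: tracewoc
Title: Wisdom-of-the-Crowd Analysis of Traced Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the wisdom of the crowd in continuous
    motor tasks where many subjects trace a closed template curve on a
    touchscreen. Provides closed template geometries resampled by arc
    length with per-segment reference points, cohort input/output with
    data-cleaning filters, splicing of 30-second traces into raw
    individual trajectories, nearest-reference-point subsampling, robust
    (median centre of mass) trajectory aggregation, and the aggregation
    analyses: within- versus between-subject aggregation curves,
    outperformance percentiles, age-stratified group comparisons,
    trajectory diversity, subject-level bootstrap confidence intervals,
    and a skill-selection sweep. A synthetic cohort generator with
    subject-specific systematic bias fields, correlated within-trial
    wander and age-dependent skill makes the whole pipeline testable
    without behavioural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
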