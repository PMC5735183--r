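Package: stimsacc
Title: Saccade Analysis for Prefrontal Microstimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing oculomotor effects of intracortical
    electrical stimulation during visually guided saccade tasks. Implements
    velocity-threshold saccade detection on eye-position traces, a taxonomy
    separating stimulation-evoked from task-related saccades, reciprocal
    (rate) transformed latency comparisons, Fisher's exact test by
    hypergeometric enumeration, a Harrison-Kanji two-way ANOVA for circular
    data with a permutation companion, electrode-grid (rostral/caudal)
    spatial analyses, and saccade kinematics comparisons with Bonferroni
    control. A synthetic eye-trace generator with main-sequence kinematics,
    ex-Gaussian latencies and configurable stimulation effects provides
    ground-truth data so every stage of the pipeline can be validated
    without access to animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
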