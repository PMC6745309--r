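Package: tepnet
Title: TMS-EEG Evoked Potential Network Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transcranial magnetic stimulation evoked
    EEG potentials (TEPs): pulse-artifact removal, filtering, epoching and
    trial rejection, evoked averaging, TEP component detection (N45, P60,
    N100, P180), early/late slope and charge-transfer features, stimulation
    intensity input/output recruitment curves, evoked-response Pearson
    connectivity matrices with Fisher-z group averaging, short-term
    plasticity ratios from frequency-patterned stimulation protocols,
    subject-level physiological network profiles with pseudo-color region
    maps, and group statistics (one-way ANOVA with Tukey post hoc, unpaired
    t tests, test-retest reliability). Includes a seeded synthetic TEP
    cohort simulator with known ground truth and BrainVision/EDF readers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
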