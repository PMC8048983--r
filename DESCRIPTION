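Package: shamtrack
Title: Assessing Sham Blinding in tDCS Studies from Online Probe Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the integrity of placebo (sham) blinding in
    transcranial direct current stimulation (tDCS) experiments that probe
    perception repeatedly during stimulation. Implements signed
    confidence-weighted perception scores with participant-bootstrap confidence
    bands, a lagged normalized cross-correlation statistic that quantifies each
    participant's sensitivity to the stimulation time course against
    protocol-defined ideal response curves, ROC/AUC evaluation of binary
    classifiers of that sensitivity, and the accompanying inferential battery
    (paired and Welch t tests, mixed and repeated-measures ANOVA, Wilcoxon
    signed-rank tests, Pearson correlations). A seedable synthetic-study
    generator emulates the two-session, two-current-strength study layout so
    the whole pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
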