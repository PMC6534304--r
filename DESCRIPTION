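Package: vocemark
Title: Acoustic Voice Markers for Memory-Clinic Conversation Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of conversational acoustic biomarkers for the
    stratification of memory-clinic patients into functional (FMD) and
    neurodegenerative (ND) classes. Implements patient-turn isolation from
    annotated mono recordings, a 51-feature acoustic profile (speech/silence
    timing statistics, pitch-synchronous voice quality measures, and
    duration-weighted spectral descriptors), three feature-selection routes
    (SVM recursive feature elimination, tree-embedded importances,
    Mann-Whitney U ranking), and leakage-controlled evaluation by nested
    stratified cross-validation and leave-one-group-out over one-minute
    segments. A source-filter synthetic-cohort generator with ground-truth
    logs makes every stage testable without clinical audio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
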