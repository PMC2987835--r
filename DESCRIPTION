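Package: aphidmine
Title: Candidate Effector Mining from Aphid Salivary-Gland ESTs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mines candidate effector proteins from aphid expressed sequence
    tag (EST) libraries: six-frame open reading frame calling, a secretion
    gate (signal-peptide score and cleavage window plus transmembrane-domain
    exclusion), redundancy clustering by local protein alignment,
    full-length assessment, a polymorphism (diversifying-selection) filter,
    cross-species reconciliation between Myzus persicae and Acyrthosiphon
    pisum, gut-contamination flagging and chemosensory-protein motif
    annotation, with a stage-by-stage funnel report. Also implements the
    companion leaf-disc fecundity statistic (chained per-well nymph
    production rates with a blocked one-way ANOVA and a +/- 1-SE initial
    screen) and the reactive-oxygen-species max-photon summary with Welch
    t-tests, together with ground-truth synthetic generators for EST
    libraries, fecundity plates and ROS time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
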