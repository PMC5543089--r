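Package: voxrsa
Title: Representational Similarity Analysis of Event-Related fMRI Voxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for representational similarity analysis (RSA)
    of event-related fMRI. Builds model similarity matrices from concept
    features, phonetic transcriptions, shape-family labels and layered
    encoder activations; extracts per-trial voxel response patterns as the
    2-8 s integral of the BOLD response; computes pair-exclusion cosine
    similarity statistics for semantic structure, object identity and
    stimulus location with permutation-labeling null distributions; performs
    rank-based between-region comparisons; constructs spherical and
    probability-map volumes of interest; and ships a synthetic event-related
    dataset generator with controllable representational structure so every
    stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
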