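Package: seqDirector
Title: Directional Multi-Objective Sequence Design for Biosensor Engineering
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for machine-learning-guided directed evolution of
    allosteric transcription-factor biosensors under multiple competing
    objectives (for example lead sensitivity versus zinc selectivity).
    Implements plate-screen metrics (fold change, dynamic range,
    wildtype normalization, selectivity calls), construction of
    direction-labeled paired training data with noise thresholding and
    category balancing, a conditional sequence-to-sequence model driven
    by <inc>/<dec> control tokens with top-k candidate generation and
    library filtering, and a synthetic two-objective fitness-landscape
    simulator so the full design-build-test-learn loop can be exercised
    and validated end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
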