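Package: weakner
Title: Knowledge-Free Weak Supervision for Clinical Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for weakly supervising clinical named-entity
    recognition with large-language-model generated labels. Reads and writes
    BRAT-style standoff annotation, segments notes into sentences, builds
    four-section few-shot prompts and supervised-fine-tuning records, runs
    pluggable generation backends (replay, oracle, corruptor), recovers
    character-span weak labels from generated JSON via a four-step
    post-processing algorithm, selects representative gold notes by
    distance-to-median entity counts, assembles weak-then-gold two-stage
    training datasets over a pluggable sequence tagger, scores entity-level
    strict and lenient micro F1, and budgets transformer inference cost with a
    closed-form FLOPs formula and GPU-time regression. Ships a synthetic
    corpus generator with a calibrated noise model so every stage is testable
    without protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
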