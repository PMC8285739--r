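Package: gleasonr
Title: Rule-Based Extraction and Triage of Prostate Cancer Gleason Scores
    from Clinical Free Text
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lexicon-driven natural language processing pipeline that
    extracts prostate cancer Gleason scores (primary, secondary, total)
    from free-text clinical and pathology notes, classifies each mention's
    specimen source (prostate surgery versus needle biopsy) with a
    tiered-priority cue lexicon and widening context windows, aggregates
    patient-level maximum scores per specimen type, and triages each
    (patient, specimen) extraction task as uncomplicated (automatable) or
    complicated (inaccurate, incomplete, or conflicting; routed to human
    review). Ships a seeded synthetic note generator with gold labels and
    controlled corruption injection, and an evaluation harness comparing
    human-alone, NLP-alone, and NLP-assisted extraction strategies with
    exact Fisher tests and workload metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
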