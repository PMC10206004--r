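Package: notescore
Title: Note-Based Scoring of Treatment Response from Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based scoring of treatment response to cholinesterase
    inhibitors and selective serotonin reuptake inhibitors from free-text
    clinical notes of dementia outpatients. Implements a keyword lexicon
    with phrase matching, sentence-level comment annotation (symptom domain,
    direction of change, intensity), medication-episode construction with a
    washout rule, prioritized evidence selection, three-point (NOTE) and
    seven-point (CIBIC-plus) change scales, responder classification,
    MoCA-to-MMSE conversion and MMSE-change computation, and a validation
    battery (Krippendorff's alpha with an ordinal metric and missing data,
    ICC(2,k), per-category Dice coefficients, Spearman correlation, BCa
    bootstrap intervals, multinomial baseline-category logit with type-II
    likelihood-ratio tests). A synthetic EMR corpus generator with known
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
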