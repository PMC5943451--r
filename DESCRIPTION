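Package: suicidenlp
Title: Rule-Based and Hybrid Text Mining of Suicidality in Psychiatric Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting recorded suicide ideation and suicide attempts in
    free-text psychiatric clinical documents. Implements a rule-based ideation
    classifier (same-sentence wildcard matching of "suicid*" and "ideat*" with
    negation-gazetteer veto), a hybrid suicide-attempt classifier (dictionary
    concept extraction, ConText-style assertion flags, bag-of-words linear SVM
    over sentence context windows with cross-validated model selection and Platt
    probability calibration, followed by rule-based post-processing filters for
    questionnaire titles, ambiguous phrases and pre-match negation), an
    evaluation harness (confusion counts, precision/recall/F1, Cohen's kappa,
    patient-level rollup), and a seeded generator of synthetic psychiatric notes
    with gold labels for end-to-end testing without access to restricted
    electronic health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
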