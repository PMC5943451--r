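# suicidenlp

Text mining of recorded suicidality in psychiatric clinical notes.

Suicide ideation and suicide attempts are central outcomes for psychiatric
epidemiology, but in electronic health records they live mostly in free-text
Event and Correspondence notes, not in structured codes. `suicidenlp`
implements two classifiers over such notes, plus everything needed to
evaluate them:

* **Rule-based ideation classifier.** A sentence mentions suicide ideation
  when it contains a token matching `suicid*` followed by a token matching
  `ideat*` (wildcards are prefix matches). The mention is vetoed as
  `non_true_event` when either of two replaceable negation gazetteers
  (sentence-scope cues such as *no, not, nil, denie\*, denied, without,
  never*; phrase cues such as *would not, didn't, does not*) matches
  anywhere in the same sentence.

* **Hybrid attempt classifier.** A replaceable dictionary of attempt
  phrases (`suicide attempt*`, `attempted suicide`, `attempt* to end her
  life`, `overdose*`, ...) proposes concept mentions. Each mention gets
  ConText-style assertion flags (negated / historical / experiencer-other),
  and a linear SVM over bag-of-words features (Porter stems plus stem/POS
  pairs plus the three flags) classifies it. Model selection explores
  stop-word removal on/off crossed with SVM cost {0.1, 1, 10} by stratified
  5-fold cross-validated F1; the winner is refit and a Platt sigmoid on the
  out-of-fold decision values calibrates a per-record probability of being
  correct. At prediction time up to six sentence windows around the concept
  sentence are scored and the most confident window wins. A rule-based
  post-processing layer then vetoes machine positives matching neutral
  questionnaire titles ("Suicide attempts/ideation", "b) Suicide attempts
  x"), ambiguous phrases ("previously also attempted to") or negation
  immediately before the matched term.

* **Evaluation harness.** Confusion counts a/b/c/d (classifier rows, gold
  columns), precision a/(a+c), recall a/(a+b), F1, Cohen's kappa
  (pairwise for 3+ annotators), and a per-patient ever-event rollup.

* **Synthetic-note generator.** The source EHR corpus is access-restricted,
  so a seeded generator emulates its mention taxonomy — affirmed/negated
  ideation and attempts, neutral titles, historical mentions, non-patient
  experiencers, self-harm without intent — with gold labels, making every
  stage testable end to end.

## Worked example

```r
library(suicidenlp)

corpus <- data.frame(
  doc_id = c("e1", "e2", "c1"),
  patient_id = c("p1", "p1", "p2"),
  doc_type = c("event", "event", "correspondence"),
  text = c("Seen at home today. Reports ongoing suicidal ideation with a plan.",
           "Denied any suicidal ideation on review.",
           paste("Past suicide attempts",
                 "Have you ever attempted suicide?",
                 "She took an overdose of 20 paracetamol tablets in a suicide attempt.",
                 sep = "\n")),
  date = NA, stringsAsFactors = FALSE)

res <- ideation_pipeline(corpus)
res$classifications[, c("doc_id", "label", "confidence")]
#>   doc_id          label confidence
#> 1     e1     true_event          1
#> 2     e2 non_true_event          1
```

Document `e1` asserts ideation; `e2` is vetoed by the negation gazetteer
("Denied"). The attempt dictionary proposes four mentions in `c1`, and the
post-processing rules strike the heading and questionnaire lines while the
narrative overdose survives:

```r
m <- detect_attempt_mentions(corpus)
cls <- data.frame(doc_id = m$doc_id, match_start = m$match_start,
                  match_end = m$match_end, label = "true_event",
                  confidence = 0.8, window_used = 1L)
filt <- apply_filters(cls, m)
cbind(m[, c("sentence_index", "match")], label = filt$classifications$label)
#>   sentence_index             match          label
#> 1              0  suicide attempts non_true_event
#> 2              1 attempted suicide non_true_event
#> 3              2          overdose     true_event
#> 4              2   suicide attempt     true_event
```

(In the full pipeline the labels come from a fitted `attempt_model()` rather
than being set by hand; see `?attempt_model` and `?predict.attempt_model`.)
Evaluation against gold labels prints the standard report:

```r
precision_recall(confusion_matrix(265, 37, 24, 174))
#>                 gold
#> classifier       true_event non_true_event
#>   true_event            265             24
#>   non_true_event         37            174
#> n = 500 instances
#> Precision (PPV) (a/a+c): 91.7%
#> Recall (Sensitivity) (a/a+b): 87.7%
#> F1: 89.7%
```

A command-line wrapper (`inst/cli/suicidenlp`, or `run_cli()` from R) wires
the stages as subcommands: `synth | ideation | attempt-train |
attempt-classify | filter | evaluate | rollup`.

## Layout

| Path | Contents |
| --- | --- |
| `R/` | implementation (corpus I/O, preprocessing, gazetteers, ConText, ideation rules, attempt model, filters, evaluation, generator, CLI) |
| `inst/extdata/` | replaceable lexicons: attempt dictionary, negation gazetteers, ConText triggers, exclusion rulebook, stop words |
| `vignettes/` | methods vignette (model, parameters, design choices, limitations) |
| `tests/testthat/` | unit, property and acceptance tests |
| `scripts/acceptance.R` | end-to-end reproduction script |
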