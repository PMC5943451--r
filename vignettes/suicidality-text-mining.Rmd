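---
title: "Detecting recorded suicidality in clinical free text: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recorded suicidality in clinical free text: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suicidenlp)
```

## The problem

Mentions of suicide ideation and suicide attempts in psychiatric records sit
overwhelmingly in free text. A mention is not an assertion: clinical notes
are full of negated mentions ("denied any suicidal ideation"), questionnaire
titles and subheadings ("Past suicide attempts", "Have you ever attempted
suicide?"), events that happened to somebody else ("her mother attempted
suicide"), remote history, and self-harm explicitly without intent to die.
The package's goal is to decide, for every mention, whether it records a
*true event* for the patient, and to aggregate surviving positives to a
per-patient ever-event flag.

Two deliberately different designs are implemented. Ideation is recorded in
highly conventionalised language, so a small rule suffices; attempts are
recorded in endlessly varied language, so a dictionary plus a learned
classifier plus corrective rules is used. Keeping both designs malleable —
every lexicon, trigger list and rulebook is a replaceable plain-text file —
is itself a goal: adapting to another database means editing word lists, not
code.

## Preprocessing

**Sentence splitting** is rule-based: boundaries after runs of `.`/`!`/`?`/`;`
followed by whitespace, and at newline runs, so a line without terminal
punctuation forms its own sentence. Clinical notes arrive in arbitrary
layouts, and questionnaire titles like "Past suicide attempts" must be their
own sentence for both the same-sentence ideation rule and the title filters
to behave; a model-based splitter trained on grammatical prose would merge
such lines into neighbouring sentences. Spans are 0-based half-open
character intervals and always slice the document text exactly (this is
fuzz-tested on random text including multi-byte characters).

**Tokens** are maximal alphanumeric runs plus standalone punctuation
characters. **Stems** come from a Porter suffix-stripping stemmer
implemented in the package (so that e.g. *ideation*/*ideations* and
*suicide*/*suicidal* share stems). **POS tags** come from a small
deterministic lexicon-plus-suffix tagger emitting Penn-style tags; the
downstream features consume tags only as opaque strings, so the contract is
determinism and one tag per token, not linguistic accuracy. All matching is
case-folded by default because clinical notes mix case freely.

**Gazetteers** are lists of token-sequence patterns where a token may end in
`*`, a prefix wildcard: `ideat*` matches *ideation* and *ideations* but not
*idea*. Patterns are re-tokenized with the text tokenizer so that entries
like `didn't` align with how the text itself is tokenized.

## The ideation rule classifier

A sentence yields an ideation mention when it contains a token matching
`suicid*` and a token matching `ideat*`. Two knobs exist because the
underlying convention can be read two ways:

* `require_order` (default `TRUE`): the `suicid*` token must precede the
  `ideat*` token. Ordering reflects how the standard phrase "suicidal
  ideation" is written.
* `require_adjacency` (default `FALSE`): adjacency would reject "suicidal
  thoughts and ideation", which is a real recording pattern, so mere
  same-sentence co-occurrence (with order) is the default.

Classification is a sentence-scope veto: if any entry of either negation
gazetteer matches anywhere in the mention's sentence, the mention is
`non_true_event`. Clause-level scoping was deliberately not used here — the
veto mirrors a simple, auditable rule. The packaged gazetteers (sentence
cues *no, not, nil, denie\*, denied, without, never*; phrase cues *would
not, didn't, does not*) are starting points, not a validated inventory;
both are user-replaceable files.

## ConText-style assertion flags

For attempt mentions, three assertion flags feed the classifier as features:
`negated`, `historical` (temporal irrelevance, which also absorbs
hypothetical triggers — the two categories stay separate in the lexicon so
they can be re-scoped), and `experiencer_other`. A pre-trigger opens a scope
over following tokens until a termination trigger (*but*, *however*, ...),
the sentence end, or its maximum scope in tokens; post-triggers work
backwards symmetrically; a flag is raised iff the mention intersects an
active scope. Defaults follow the published ConText convention: 5 tokens
for negation, effectively sentence-wide for historical/hypothetical/
experiencer. Triggers overlapping the mention itself are ignored. The scope
engine is verified against a brute-force implementation that materialises
every trigger's scope interval explicitly.

Whether assertion information should enter the learner as per-mention flags
or as token decorations is a genuinely open design point; flags-as-features
was chosen because it keeps the feature space small and the flags
independently testable.

## The hybrid attempt classifier

**Concept proposal.** Every match of the attempt dictionary yields a
mention carrying the matched text and a context excerpt of up to 500
characters (whole sentences nearest the match, then hard truncation centred
on the match; the excerpt is a literal document slice so line layout
survives into it, which the title filters rely on). The packaged dictionary
is a seed list of common attempt phrasings; it is expected to be replaced
or extended per database.

**Features.** Bag of words over the context window: Porter-stem counts,
stem/POS-pair counts, and the three binary ConText flags. Stop-word removal
is a model-selection dimension rather than a fixed choice; the packaged
stop list deliberately keeps negation words, which carry assertion signal.

**Windows.** At prediction time up to six sentence windows around the
concept sentence *s* are scored: {s}, {s−1,s}, {s,s+1}, {s−1,s,s+1},
{s−2..s}, {s..s+2}. The set is symmetric, always contains *s*, and clips at
document edges with duplicates collapsed onto the smallest window id (a
mention in a one-sentence document has exactly one window; the first
sentence of a long document has three). The window with the highest
calibrated confidence supplies the label, ties broken toward the smallest
id. Training uses a single configurable window (`train_window`, default the
concept sentence): the window sweep is an apply-time robustness device, and
training on the concept sentence keeps the learned weights interpretable as
sentence-level evidence.

**Model selection and calibration.** The grid is stop-word removal
{off, on} crossed with linear-SVM cost {0.1, 1, 10}. Linear kernels are the
standard for sparse bag-of-words text; the small cost grid spans under- to
over-fitting regimes without inviting a fishing expedition. Each cell is
scored by pooled out-of-fold F1 under stratified 5-fold cross-validation
with seeded fold assignment; ties go to the first cell in grid order
(smallest cost, stop words off). The winner is refit on all data, and a
Platt sigmoid with regularised targets is fitted to the winning cell's
out-of-fold decision values by BFGS, giving each prediction a probability
of being correct; the lowest-confidence predictions are the natural review
queue (`rank_for_review()`) for growing a gold standard.

**Degenerate inputs.** A single-class training set is an error; an empty
grid is a configuration error; a mention whose window contains no
in-vocabulary feature is scored from the model bias with a calibrated
confidence rather than erroring. Model files embed the configuration,
a format version and a content fingerprint (SHA-256 over weights,
vocabulary, calibration and selected hyper-parameters) that is checked on
reload; identical corpus, configuration and seed reproduce the fingerprint
bit for bit.

## Post-processing filters

The learned classifier's systematic failure mode is the neutral mention:
questionnaire titles and subheadings contain exactly the dictionary phrase
and nothing else. The exclusion rulebook re-expresses the corrective layer
as case-insensitive regular expressions over the two output fields (match
and context excerpt), in three categories:

* `title_neutral` — line-anchored heading patterns (optional list marker,
  optional "history of"/"past"/"previous", the bare phrase, optional
  "/ideation" or trailing "x") and questionnaire interrogatives. These are
  evaluated against the line of the excerpt containing the match: a heading
  is a property of the line the match sits on, and testing the whole
  excerpt would let a heading two lines above veto a genuine narrative
  mention.
* `ambiguous` — redundant truncated phrases such as "previously also
  attempted to".
* `negation_before_match` — negation tokens within the 5 tokens preceding
  the match, aligned with the ConText negation scope.

Filters only ever flip `true_event` to `non_true_event`: recall can only
fall and false positives can only fall, and applying the rulebook twice
equals applying it once. Filtering is a distinct post-stage rather than a
training-time device, so its effect is separately measurable and the
rulebook stays editable without retraining. The packaged rulebook covers
the documented failure modes; it is a faithful mechanism, not an exhaustive
phrase inventory, and self-harm-versus-attempt disambiguation is
deliberately out of its scope.

## Evaluation

Confusion counts follow the classifier-rows/gold-columns layout with cells
a (true positive), b (false negative), c (false positive), d (true
negative); precision = a/(a+c), recall = a/(a+b). Metrics are exact
proportions internally; display rounds to one decimal in percent. One
consequence is worth flagging: the ideation evaluation fixture with
a = 265, b = 37, c = 24, d = 174 yields recall 265/302 = 87.748%, which
prints as 87.7% — the table it reproduces reports 87.8%, reachable only by
double rounding (87.748 → 87.75 → 87.8), which this package does not do.
Zero denominators give `NA`-marked fields, never exceptions.

Cohen's kappa uses marginal-product chance agreement; identical vectors
give 1 by definition (including two identical constant vectors, where the
formula is 0/0). With three or more annotators the aggregation into one
number is ambiguous, so the package reports the pairwise set plus its mean.
Instances are evaluated at mention level, with `patient_rollup()` providing
the document-to-patient aggregation; whether multiple mentions per document
should be collapsed before evaluation is left to the caller, since both
conventions occur in practice.

## The synthetic corpus

The source records are access-restricted, so a seeded generator produces
documents assembled from templated sentences with lexical jitter (names,
drugs, counts, years, places), one sentence per line, each non-filler
document embedding exactly one suicidality sentence with a recorded
category and gold label.

What it emulates, and why:

* the full mention taxonomy, including the documented failure modes
  (titles, questionnaire items, pre-match negation, self-harm without
  intent);
* a document mix of 55% event / 45% correspondence notes;
* neutral titles at ≥30% of attempt-concept mentions — the neutral-heavy
  regime that motivates post-processing;
* affirmed attempts dominating the remaining attempt mentions (~72%),
  approximating the reported composition of the attempt gold standard
  (388/500 true instances);
* telegraphic affirmations typical of event notes ("suicide attempt by
  overdose of sertraline last night") alongside full narrative sentences.
  These terse lines share their surface with questionnaire titles, which is
  precisely the ambiguity that makes bare titles get over-called by a model
  that has not seen titles — without them, a bag-of-words SVM separates the
  classes on cue words alone and the title problem cannot be reproduced.

What it does not emulate: real formatting and metadata, misspellings,
abbreviations, clinical plausibility beyond the taxonomy, or real-world
category base rates (which are unknowable without data access; the defaults
are stated choices, not estimates). Consequently, passing tests demonstrate
that the mechanisms are implemented correctly and behave as designed under
the stated conditions — they do not certify performance on real records,
where vocabulary, negation styles and layout are far messier.

Two structural properties are guaranteed by construction and asserted in
tests: every affirmed sentence contains at least one packaged-dictionary
term (so detector recall on synthetic truth is 1), and affirmed/negated
ideation sentences draw only on the packaged lexicons (so the rule
classifier's labels equal generator truth exactly).

## Determinism and problem sizes

Every stochastic step — generation, fold assignment, fixture shuffling —
is driven by an explicit integer seed, and seeded runs are byte-
reproducible end to end (corpus files, model fingerprints, result files).
The shipped tests and the reproduction script use 500-document corpora for
corpus-level checks, 500 random sentences for the ConText oracle, ten seeds
of 500 instances for planted-keyword recovery, and 10,000 labels for the
kappa null check; these sizes give stable statistics for each property
while keeping a full run in minutes.

## Known limitations

* The ideation rule detects one conventional phrasing pattern; paraphrases
  without a `suicid*` token ("wants to end it all") are invisible to it.
* Sentence-scope negation over-vetoes long coordinated sentences
  ("denies X but reports ongoing suicidal ideation" is vetoed).
* The attempt dictionary and all trigger/exclusion lists are seed
  inventories; recall on a new database depends on extending them.
* No temporal resolution beyond the historical flag: a surviving positive
  means "recorded as a true event somewhere", not "happened at time t".
* Self-harm without intent is distinguished only insofar as negation and
  filter patterns catch it; a residue of such mentions surviving as false
  positives is expected behaviour, not a bug.
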