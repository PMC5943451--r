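# Shared fixtures and independent oracles used across the test files.
# Everything is built in code; no stored data files.

tiny_corpus <- function(texts, doc_type = "event") {
  data.frame(doc_id = sprintf("d%03d", seq_along(texts)),
             patient_id = sprintf("p%03d", seq_along(texts)),
             doc_type = rep_len(doc_type, length(texts)),
             text = texts, date = NA_character_, stringsAsFactors = FALSE)
}

prec_rec_of <- function(truth, pred) {
  a <- sum(truth == "true_event" & pred == "true_event")
  b <- sum(truth == "true_event" & pred != "true_event")
  c_ <- sum(truth != "true_event" & pred == "true_event")
  c(precision = a / (a + c_), recall = a / (a + b))
}

f1_of <- function(truth, pred) {
  a <- sum(truth == "true_event" & pred == "true_event")
  b <- sum(truth == "true_event" & pred != "true_event")
  c_ <- sum(truth != "true_event" & pred == "true_event")
  2 * a / (2 * a + b + c_)
}

# Category weights emulating a training set annotated before questionnaire
# documents flooded in: no neutral titles, everything else at default rates.
neutral_free_weights <- function() {
  c(affirmed_ideation = 0.12, negated_ideation = 0.06,
    affirmed_attempt = 0.28, negated_attempt = 0.04, neutral_title = 0,
    historical = 0.02, experiencer_other = 0.02, self_harm_no_intent = 0.03,
    filler = 0.43)
}

mention_categories <- function(mentions, manifest) {
  manifest$category[match(paste(mentions$doc_id, mentions$sentence_index),
                          paste(manifest$doc_id, manifest$sentence_index))]
}

# Corpus where the label depends only on a planted keyword; used for the
# weight-recovery property.
planted_keyword_corpus <- function(seed, n = 500, keyword = "hospitalised") {
  set.seed(seed)
  fillers <- c("seen", "today", "review", "calm", "settled", "plan", "ward",
               "team", "meeting", "notes", "visit", "sleep", "mood", "stable",
               "weekly", "clinic")
  rows <- lapply(seq_len(n), function(i) {
    pos <- i %% 2 == 0
    words <- sample(fillers, 6, replace = TRUE)
    if (pos) words[sample.int(6, 1)] <- keyword
    data.frame(doc_id = sprintf("d%04d", i),
               patient_id = sprintf("p%03d", i %% 100),
               doc_type = "event",
               text = paste(c(words[1:3], "suicide attempt", words[4:6]),
                            collapse = " "),
               date = NA_character_, stringsAsFactors = FALSE)
  })
  list(corpus = do.call(rbind, rows),
       labels = ifelse(seq_len(n) %% 2 == 0, "true_event", "non_true_event"))
}

# Brute-force ConText oracle: explicit interval construction per trigger,
# independent of the forward/backward walk in apply_context().
oracle_context_flags <- function(mention_first, mention_last, surfaces,
                                 lexicon = default_trigger_lexicon()) {
  m <- match_gazetteer(lexicon$gazetteer, surfaces)
  trig <- data.frame(first = m$first, last = m$last,
                     category = lexicon$table$category[m$entry],
                     max_scope = lexicon$table$max_scope[m$entry],
                     stringsAsFactors = FALSE)
  trig <- trig[trig$last < mention_first | trig$first > mention_last, ,
               drop = FALSE]
  n <- length(surfaces)
  term_starts <- trig$first[trig$category == "termination"]
  term_ends <- trig$last[trig$category == "termination"]
  flags <- list(negated = FALSE, historical = FALSE, experiencer_other = FALSE)
  flagmap <- c(negation_pre = "negated", negation_post = "negated",
               historical = "historical", hypothetical = "historical",
               experiencer = "experiencer_other")
  for (k in seq_len(nrow(trig))) {
    cat <- trig$category[k]
    if (cat == "termination") next
    if (cat == "negation_post") {
      lo <- max(1L, trig$first[k] - trig$max_scope[k])
      cut <- term_ends[term_ends < trig$first[k]]
      if (length(cut)) lo <- max(lo, max(cut) + 1L)
      hi <- trig$first[k] - 1L
    } else {
      lo <- trig$last[k] + 1L
      hi <- min(n, trig$last[k] + trig$max_scope[k])
      cut <- term_starts[term_starts > trig$last[k]]
      if (length(cut)) hi <- min(hi, min(cut) - 1L)
    }
    if (lo <= hi && mention_first <= hi && mention_last >= lo) {
      flags[[flagmap[[cat]]]] <- TRUE
    }
  }
  flags
}

random_context_sentence <- function() {
  vocab <- c("not", "no", "denies", "denied", "without", "never", "past",
             "previous", "previously", "mother", "father", "family", "if",
             "whether", "but", "however", "though", "history", "of", "ruled",
             "out", "was", "unlikely", "in", "case", "apart", "from",
             "alpha", "beta", "gamma", "delta", "zeta", "attempt", "harm")
  n <- sample(5:15, 1)
  surfaces <- sample(vocab, n, replace = TRUE)
  first <- sample.int(n, 1)
  last <- min(n, first + sample(0:1, 1))
  list(surfaces = surfaces, first = first, last = last)
}
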