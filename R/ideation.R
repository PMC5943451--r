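# Rule-based suicide-ideation classifier: a sentence mentions ideation when
# it contains a token matching "suicid*" and a token matching "ideat*" (by
# default in that order); the mention is negated when either negation
# gazetteer matches anywhere in the same sentence.

#' Configuration for the ideation rule classifier
#'
#' @param positive_pattern two wildcard token patterns that must co-occur in
#'   a sentence; default `c("suicid*", "ideat*")`.
#' @param neg_sentence sentence-scope negation gazetteer (path or
#'   [gazetteer()]); any match in the sentence vetoes the mention.
#' @param neg_phrase phrase-scope negation gazetteer, applied the same way;
#'   the two lists are kept separate so either can be replaced independently.
#' @param require_order must the `suicid*` token precede the `ideat*` token?
#' @param require_adjacency must the two tokens be adjacent? The default
#'   (`FALSE`) accepts e.g. "suicidal thoughts and ideation".
#' @param context_budget maximum context-excerpt length in characters.
#' @return object of class `ideation_config`.
#' @export
ideation_config <- function(positive_pattern = c("suicid*", "ideat*"),
                            neg_sentence = default_ideation_negation("sentence"),
                            neg_phrase = default_ideation_negation("phrase"),
                            require_order = TRUE,
                            require_adjacency = FALSE,
                            context_budget = 500L) {
  if (length(positive_pattern) != 2L) {
    stopf("positive_pattern must contain exactly two token patterns")
  }
  as_gaz <- function(g, nm) {
    if (inherits(g, "gazetteer")) g else read_gazetteer(g, name = nm)
  }
  structure(list(positive_pattern = positive_pattern,
                 neg_sentence = as_gaz(neg_sentence, "neg_sentence"),
                 neg_phrase = as_gaz(neg_phrase, "neg_phrase"),
                 require_order = isTRUE(require_order),
                 require_adjacency = isTRUE(require_adjacency),
                 context_budget = as.integer(context_budget)),
            class = "ideation_config")
}

#' Packaged negation gazetteers for the ideation classifier
#'
#' @param which `"sentence"` (sentence-scope cues: no, not, nil, denie*,
#'   denied, without, never) or `"phrase"` (phrase cues: would not, didn't,
#'   does not). Both are replaceable via [ideation_config()].
#' @return a [gazetteer()].
#' @export
default_ideation_negation <- function(which = c("sentence", "phrase")) {
  which <- match.arg(which)
  read_gazetteer(pkg_extdata(sprintf("ideation_negation_%s.txt", which)))
}

#' Detect suicide-ideation mentions
#'
#' Emits one mention per sentence that contains both positive-pattern tokens
#' (order/adjacency per config); the match is the minimal token span covering
#' both tokens.
#'
#' @param corpus clinical corpus data.frame.
#' @param config an [ideation_config()].
#' @param annotations optional precomputed [annotate_corpus()] result.
#' @return concept-mention data.frame (`concept == "ideation"`).
#' @export
detect_ideation <- function(corpus, config = ideation_config(),
                            annotations = NULL) {
  stopifnot(inherits(config, "ideation_config"))
  if (is.null(annotations)) annotations <- annotate_corpus(corpus)
  out <- list()
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus[i, ]
    ann <- annotations[[doc$doc_id]]
    if (!nrow(ann$tokens)) next
    sent_idx <- integer(0); t_first <- integer(0); t_last <- integer(0)
    for (s in unique(ann$tokens$sentence)) {
      toks <- ann$tokens[ann$tokens$sentence == s, , drop = FALSE]
      surf <- fold_case(toks$surface)
      ia <- which(vapply(surf, function(x)
        match_one_token(fold_case(config$positive_pattern[1]), x), logical(1)))
      ib <- which(vapply(surf, function(x)
        match_one_token(fold_case(config$positive_pattern[2]), x), logical(1)))
      if (!length(ia) || !length(ib)) next
      pairs <- expand.grid(a = ia, b = ib)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      if (config$require_order) pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
      if (config$require_adjacency) {
        pairs <- pairs[abs(pairs$b - pairs$a) == 1L, , drop = FALSE]
      }
      if (!nrow(pairs)) next
      width <- abs(pairs$b - pairs$a)
      best <- pairs[which.min(width), ]
      sent_idx <- c(sent_idx, s)
      t_first <- c(t_first, min(best$a, best$b))
      t_last <- c(t_last, max(best$a, best$b))
    }
    out[[length(out) + 1L]] <- make_mentions(doc, ann, "ideation", sent_idx,
                                             t_first, t_last,
                                             budget = config$context_budget)
  }
  if (!length(out)) return(empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify ideation mentions with the negation-gazetteer veto
#'
#' A mention is `non_true_event` iff an entry of either negation gazetteer
#' matches within the mention's sentence (sentence scope), else `true_event`.
#' Rule classifications carry confidence 1.
#'
#' @param mentions output of [detect_ideation()].
#' @inheritParams detect_ideation
#' @return classification data.frame keyed by `doc_id`, `match_start`,
#'   `match_end`, with `label`, `confidence`, `window_used` (NA).
#' @export
classify_ideation <- function(mentions, corpus, config = ideation_config(),
                              annotations = NULL) {
  stopifnot(inherits(config, "ideation_config"))
  if (!nrow(mentions)) return(empty_classifications())
  if (is.null(annotations)) {
    annotations <- annotate_corpus(corpus[corpus$doc_id %in% mentions$doc_id, ,
                                          drop = FALSE])
  }
  labels <- character(nrow(mentions))
  for (k in seq_len(nrow(mentions))) {
    ann <- annotations[[mentions$doc_id[k]]]
    toks <- ann$tokens[ann$tokens$sentence == mentions$sentence_index[k], ,
                       drop = FALSE]
    negated <- nrow(match_gazetteer(config$neg_sentence, toks$surface)) > 0L ||
      nrow(match_gazetteer(config$neg_phrase, toks$surface)) > 0L
    labels[k] <- if (negated) "non_true_event" else "true_event"
  }
  data.frame(doc_id = mentions$doc_id, match_start = mentions$match_start,
             match_end = mentions$match_end, label = labels,
             confidence = 1, window_used = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Run the full ideation rule classifier over a corpus
#'
#' @inheritParams detect_ideation
#' @return list with `mentions` and `classifications`.
#' @export
ideation_pipeline <- function(corpus, config = ideation_config()) {
  annotations <- annotate_corpus(corpus)
  mentions <- detect_ideation(corpus, config, annotations)
  classifications <- classify_ideation(mentions, corpus, config, annotations)
  list(mentions = mentions, classifications = classifications)
}
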