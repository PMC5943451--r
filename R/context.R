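# ConText-style assertion flags for concept mentions: negated, historical
# (temporally irrelevant, including hypothetical triggers) and
# experiencer-other. Triggers come from a replaceable lexicon; a pre-trigger
# opens a scope over the following tokens until a termination trigger, the
# sentence end, or its maximum scope in tokens; post-triggers act backwards
# symmetrically. A flag is raised iff the mention falls inside an active
# scope of that category.

.trigger_categories <- c("negation_pre", "negation_post", "historical",
                         "hypothetical", "experiencer", "termination")

.category_flag <- c(negation_pre = "negated", negation_post = "negated",
                    historical = "historical", hypothetical = "historical",
                    experiencer = "experiencer_other")

#' Read a ConText trigger lexicon
#'
#' Tab-separated file with a header and columns `pattern`, `category`,
#' `max_scope`. Categories are `negation_pre`, `negation_post`, `historical`,
#' `hypothetical`, `experiencer` and `termination`; `max_scope` is the scope
#' length in tokens (use a large value for sentence-wide scope). Patterns may
#' span several tokens and use terminal `*` wildcards.
#'
#' @param path path to the TSV file.
#' @return object of class `trigger_lexicon`.
#' @export
read_trigger_lexicon <- function(path) {
  if (!file.exists(path)) stopf("trigger lexicon not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                          encoding = "UTF-8")
  for (f in c("pattern", "category", "max_scope")) {
    if (is.null(df[[f]])) stopf("trigger lexicon is missing column '%s'", f)
  }
  bad <- which(!df$category %in% .trigger_categories)
  if (length(bad)) stopf("unknown trigger category '%s'", df$category[bad[1]])
  df$max_scope <- as.integer(df$max_scope)
  if (any(is.na(df$max_scope) | df$max_scope < 1L)) {
    stopf("max_scope must be a positive integer")
  }
  gaz <- gazetteer(as.list(df$pattern), name = "context_triggers")
  structure(list(table = df, gazetteer = gaz), class = "trigger_lexicon")
}

#' Packaged default ConText trigger lexicon
#'
#' Seeded from the published ConText term lists: negation scope 5 tokens,
#' historical/hypothetical/experiencer scope sentence-wide.
#'
#' @return object of class `trigger_lexicon`.
#' @export
default_trigger_lexicon <- function() {
  read_trigger_lexicon(pkg_extdata("context_triggers.tsv"))
}

# All trigger occurrences over one sentence's token surfaces.
find_triggers <- function(lexicon, surfaces) {
  m <- match_gazetteer(lexicon$gazetteer, surfaces)
  if (!nrow(m)) {
    return(data.frame(first = integer(0), last = integer(0),
                      category = character(0), max_scope = integer(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  }
  data.frame(first = m$first, last = m$last,
             category = lexicon$table$category[m$entry],
             max_scope = lexicon$table$max_scope[m$entry],
             pattern = lexicon$table$pattern[m$entry],
             stringsAsFactors = FALSE)
}

#' Apply ConText assertion rules to a mention
#'
#' Walks the sentence tokens with a scope state machine: each pre-trigger
#' activates its flag for up to `max_scope` following tokens, cut short by a
#' termination trigger or the sentence end; post-triggers cover preceding
#' tokens symmetrically. Triggers overlapping the mention itself are ignored.
#'
#' @param mention_first,mention_last 1-based token indices of the mention
#'   within the sentence.
#' @param surfaces sentence token surfaces.
#' @param lexicon a `trigger_lexicon` (default packaged lexicon).
#' @return list with logical flags `negated`, `historical`,
#'   `experiencer_other` and `triggering_terms`, a data.frame of the triggers
#'   whose scope covers the mention.
#' @examples
#' toks <- tokenize("she would not attempt to take her life")$surface
#' apply_context(4, 8, toks)
#' @export
apply_context <- function(mention_first, mention_last, surfaces,
                          lexicon = default_trigger_lexicon()) {
  stopifnot(mention_first >= 1L, mention_last <= length(surfaces),
            mention_first <= mention_last)
  trig <- find_triggers(lexicon, surfaces)
  # drop triggers overlapping the concept itself
  keep <- trig$last < mention_first | trig$first > mention_last
  trig <- trig[keep, , drop = FALSE]
  n <- length(surfaces)

  flags <- c(negated = FALSE, historical = FALSE, experiencer_other = FALSE)
  hits <- list()

  term_starts <- trig$first[trig$category == "termination"]

  pre <- trig[trig$category %in% c("negation_pre", "historical",
                                   "hypothetical", "experiencer"), , drop = FALSE]
  if (nrow(pre)) {
    # forward walk: active[k] = remaining scope tokens for pre-trigger k
    active <- integer(nrow(pre))
    for (i in seq_len(n)) {
      if (i %in% term_starts) active[] <- 0L
      covered <- which(active > 0L)
      if (length(covered) && i >= mention_first && i <= mention_last) {
        for (k in covered) {
          fl <- .category_flag[[pre$category[k]]]
          flags[[fl]] <- TRUE
          hits[[length(hits) + 1L]] <- pre[k, c("pattern", "category")]
        }
      }
      active[active > 0L] <- active[active > 0L] - 1L
      opening <- which(pre$last == i)
      if (length(opening)) active[opening] <- pre$max_scope[opening]
    }
  }

  post <- trig[trig$category == "negation_post", , drop = FALSE]
  if (nrow(post)) {
    term_ends <- trig$last[trig$category == "termination"]
    for (k in seq_len(nrow(post))) {
      lo <- max(1L, post$first[k] - post$max_scope[k])
      cut <- term_ends[term_ends < post$first[k]]
      if (length(cut)) lo <- max(lo, max(cut) + 1L)
      hi <- post$first[k] - 1L
      if (hi >= lo && mention_first <= hi && mention_last >= lo) {
        flags[["negated"]] <- TRUE
        hits[[length(hits) + 1L]] <- post[k, c("pattern", "category")]
      }
    }
  }

  terms <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(pattern = character(0), category = character(0),
               stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  list(negated = unname(flags[["negated"]]),
       historical = unname(flags[["historical"]]),
       experiencer_other = unname(flags[["experiencer_other"]]),
       triggering_terms = terms)
}
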