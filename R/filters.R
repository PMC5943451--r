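# Rule-based post-processing: veto machine-labelled attempt positives whose
# match or context excerpt fits a neutral-title, ambiguous-phrase or
# negation-before-match pattern. Filters only ever flip true_event to
# non_true_event, so recall can only decrease and precision-relevant false
# positives can only decrease.

.rule_categories <- c("title_neutral", "ambiguous", "negation_before_match")
.negation_prematch_tokens <- 5L  # tokens inspected before the match

#' Read an exclusion rulebook
#'
#' Tab-separated file with header and columns `rule_id`, `field` (`match` or
#' `context_string`), `pattern` (case-insensitive Perl regular expression;
#' use `(?m)` for line-anchored heading patterns) and `category`
#' (`title_neutral`, `ambiguous`, `negation_before_match`). Two categories
#' narrow what the pattern sees: `negation_before_match` patterns are tested
#' against the last 5 tokens of the chosen field preceding the match
#' (mirroring the ConText negation scope), and `title_neutral` patterns on
#' `context_string` are tested against the line of the excerpt containing
#' the match, so a heading elsewhere in the excerpt cannot veto a narrative
#' mention.
#'
#' @param path path to the TSV file.
#' @return object of class `exclusion_rulebook`.
#' @export
read_rulebook <- function(path) {
  if (!file.exists(path)) stopf("rulebook not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                          encoding = "UTF-8")
  for (f in c("rule_id", "field", "pattern", "category")) {
    if (is.null(df[[f]])) stopf("rulebook is missing column '%s'", f)
  }
  if (anyDuplicated(df$rule_id)) stopf("duplicate rule_id in rulebook")
  if (any(!df$field %in% c("match", "context_string"))) {
    stopf("rulebook field must be 'match' or 'context_string'")
  }
  if (any(!df$category %in% .rule_categories)) {
    stopf("unknown rule category")
  }
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ grepl(df$pattern[i], "", perl = TRUE); TRUE },
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stopf("rule '%s' has an invalid pattern", df$rule_id[i])
  }
  structure(list(rules = df), class = "exclusion_rulebook")
}

#' Packaged default exclusion rulebook
#'
#' Covers questionnaire/heading title lines (list markers, "History of
#' previous suicide attempts", "Suicide attempts/ideation"), interrogative
#' questionnaire items ("Have you ever attempted suicide?"), the redundant
#' ambiguous phrases, and negation tokens immediately preceding the matched
#' attempt term.
#'
#' @return object of class `exclusion_rulebook`.
#' @export
default_rulebook <- function() {
  read_rulebook(pkg_extdata("exclusion_rules.tsv"))
}

#' @export
print.exclusion_rulebook <- function(x, ...) {
  cat(sprintf("<exclusion rulebook: %d rules>\n", nrow(x$rules)))
  print(x$rules[, c("rule_id", "field", "category")], row.names = FALSE)
  invisible(x)
}

# Text the rule is evaluated against for one mention. Two categories narrow
# the slice of the chosen field: title rules see only the line the match
# sits on (a heading pattern asserts something about that line, not about a
# heading elsewhere in the excerpt), and pre-match negation rules see the
# last few tokens before the match.
rule_target_text <- function(rule, mention) {
  txt <- if (rule$field == "match") mention$match else mention$context_string
  rel <- mention$match_start - mention$context_start
  if (rule$category == "negation_before_match") {
    pre <- substr(txt, 1L, max(rel, 0L))
    toks <- tokenize(pre)$surface
    txt <- paste(utils::tail(toks, .negation_prematch_tokens), collapse = " ")
  } else if (rule$category == "title_neutral" && rule$field == "context_string") {
    breaks <- c(0L, which(strsplit(txt, "")[[1]] %in% c("\n", "\r")),
                nchar(txt) + 1L)
    from <- max(breaks[breaks <= rel]) + 1L
    to <- min(breaks[breaks > rel + 1L]) - 1L
    txt <- substr(txt, from, to)
  }
  txt
}

#' Apply the exclusion rulebook to classified mentions
#'
#' Any `true_event` classification whose mention matches any rule is
#' relabelled `non_true_event`; non-positives are untouched. Applying the
#' rulebook twice equals applying it once.
#'
#' @param classifications classification table (keyed to mentions).
#' @param mentions concept-mention table.
#' @param rulebook an `exclusion_rulebook`.
#' @return list with `classifications` (filtered) and `log`, a data.frame of
#'   (doc_id, match_start, match_end, rule_id, category) exclusions.
#' @export
apply_filters <- function(classifications, mentions,
                          rulebook = default_rulebook()) {
  stopifnot(inherits(rulebook, "exclusion_rulebook"))
  mk <- mention_key(mentions)
  ck <- mention_key(classifications)
  orphan <- setdiff(ck, mk)
  if (length(orphan)) stopf("classification without a matching mention")
  idx <- match(ck, mk)
  log_rows <- list()
  out <- classifications
  for (i in seq_len(nrow(out))) {
    if (out$label[i] != "true_event") next
    mention <- mentions[idx[i], ]
    for (r in seq_len(nrow(rulebook$rules))) {
      rule <- rulebook$rules[r, ]
      target <- rule_target_text(rule, mention)
      if (grepl(rule$pattern, target, perl = TRUE, ignore.case = TRUE)) {
        out$label[i] <- "non_true_event"
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          doc_id = out$doc_id[i], match_start = out$match_start[i],
          match_end = out$match_end[i], rule_id = rule$rule_id,
          category = rule$category, stringsAsFactors = FALSE)
        break
      }
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(doc_id = character(0), match_start = integer(0),
               match_end = integer(0), rule_id = character(0),
               category = character(0), stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(classifications = out, log = log)
}
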