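# Corpus I/O: clinical documents, gold labels and classifier result tables.
#
# A clinical corpus is a data.frame with columns doc_id, patient_id, doc_type
# ("event" or "correspondence"), text, and optional date (ISO-8601 string).
# Interchange is JSONL (one document object per line) with CSV as secondary.

.doc_types <- c("event", "correspondence")
.required_doc_fields <- c("doc_id", "patient_id", "doc_type", "text")

validate_corpus <- function(df) {
  for (f in .required_doc_fields) {
    if (is.null(df[[f]])) stopf("corpus is missing required field '%s'", f)
  }
  bad <- which(!df$doc_type %in% .doc_types)
  if (length(bad)) {
    stopf("unknown doc_type '%s' at record %d", df$doc_type[bad[1]], bad[1])
  }
  if (anyDuplicated(df$doc_id)) {
    stopf("duplicate doc_id '%s'", df$doc_id[duplicated(df$doc_id)][1])
  }
  if (any(is.na(df$text))) stopf("text may be empty but not absent")
  df
}

#' Read a clinical corpus
#'
#' @param path input file.
#' @param format `"jsonl"` (one JSON object per line, the primary interchange
#'   format because free text with embedded newlines is fragile in CSV) or
#'   `"csv"`.
#' @return data.frame with columns `doc_id`, `patient_id`, `doc_type`,
#'   `text`, `date` (NA when absent), one row per record in file order.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stopf("record %d is not valid JSON: %s",
                                                i, conditionMessage(e)))
      for (f in .required_doc_fields) {
        if (is.null(rec[[f]])) stopf("record %d is missing field '%s'", i, f)
      }
      recs[[i]] <- data.frame(
        doc_id = as.character(rec$doc_id),
        patient_id = as.character(rec$patient_id),
        doc_type = as.character(rec$doc_type),
        text = as.character(rec$text),
        date = if (is.null(rec$date)) NA_character_ else as.character(rec$date),
        stringsAsFactors = FALSE)
    }
    df <- if (length(recs)) do.call(rbind, recs) else
      data.frame(doc_id = character(0), patient_id = character(0),
                 doc_type = character(0), text = character(0),
                 date = character(0), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
    for (f in .required_doc_fields) {
      if (is.null(df[[f]])) stopf("record %d is missing field '%s'",
                                  if (nrow(df)) 1L else 0L, f)
    }
    if (is.null(df$date)) df$date <- NA_character_
    df$date[!is.na(df$date) & df$date == ""] <- NA_character_
    df <- df[, c("doc_id", "patient_id", "doc_type", "text", "date")]
  }
  validate_corpus(df)
}

#' Write a clinical corpus
#'
#' Inverse of [read_corpus()]; `write_corpus` then `read_corpus` round-trips
#' all fields in both formats.
#'
#' @param corpus corpus data.frame.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(doc_id = corpus$doc_id[i], patient_id = corpus$patient_id[i],
                  doc_type = corpus$doc_type[i], text = corpus$text[i])
      if (!is.na(corpus$date[i])) rec$date <- corpus$date[i]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(corpus, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Build the context excerpt around a match
#'
#' Assembles whole sentences nearest the match (preferring the earlier
#' sentence on ties) until adding another sentence would exceed the character
#' budget; if the mention's own sentence already exceeds the budget the
#' excerpt is hard-truncated to `budget` characters centred on the match. The
#' excerpt is the literal document slice, so line layout (headings) survives
#' into the context string.
#'
#' @param text full document text.
#' @param sentences sentence table from [split_sentences()].
#' @param sentence_index 0-based index of the sentence containing the match.
#' @param match_start,match_end 0-based half-open span of the match.
#' @param budget maximum excerpt length in characters (default 500).
#' @return list with `context_string` and `context_start` (document offset of
#'   the excerpt's first character).
#' @export
build_context_string <- function(text, sentences, sentence_index,
                                 match_start, match_end, budget = 500L) {
  row <- which(sentences$index == sentence_index)
  if (!length(row)) stopf("sentence index %d not found", sentence_index)
  lo <- hi <- row
  span_len <- function(a, b) sentences$end[b] - sentences$start[a]
  if (span_len(lo, hi) <= budget) {
    repeat {
      can_prev <- lo > 1L && span_len(lo - 1L, hi) <= budget
      can_next <- hi < nrow(sentences) && span_len(lo, hi + 1L) <= budget
      if (can_prev) lo <- lo - 1L
      else if (can_next) hi <- hi + 1L
      else break
    }
    start <- sentences$start[lo]; end <- sentences$end[hi]
  } else {
    centre <- (match_start + match_end) %/% 2L
    start <- max(sentences$start[row],
                 min(centre - budget %/% 2L, sentences$end[row] - budget))
    end <- min(sentences$end[row], start + budget)
  }
  list(context_string = slice_text(text, start, end), context_start = start)
}

# Build the concept-mention table for a set of token-run matches in one
# document. Used by both the ideation and attempt detectors.
make_mentions <- function(doc, ann, concept, sent_index, tok_first, tok_last,
                          budget = 500L) {
  if (!length(sent_index)) return(empty_mentions())
  rows <- lapply(seq_along(sent_index), function(k) {
    toks <- ann$tokens[ann$tokens$sentence == sent_index[k], , drop = FALSE]
    ms <- toks$start[tok_first[k]]
    me <- toks$end[tok_last[k]]
    ctx <- build_context_string(doc$text, ann$sentences, sent_index[k],
                                ms, me, budget = budget)
    data.frame(doc_id = doc$doc_id, patient_id = doc$patient_id,
               concept = concept, sentence_index = sent_index[k],
               match = slice_text(doc$text, ms, me),
               match_start = ms, match_end = me,
               context_string = ctx$context_string,
               context_start = ctx$context_start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.result_cols <- c("doc_id", "patient_id", "concept", "sentence_index",
                  "match", "match_start", "match_end", "context_string",
                  "context_start", "label", "confidence", "window_used")

#' Write classified mentions to a results table
#'
#' Joins classifications to their mentions by the (doc_id, match span) key
#' and writes one row per classified mention with, at minimum, doc_id,
#' patient_id, concept, match, context_string, label and confidence.
#'
#' @param mentions concept-mention table.
#' @param classifications classification table keyed by `doc_id`,
#'   `match_start`, `match_end`.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return the combined data.frame, invisibly.
#' @export
write_results <- function(mentions, classifications, path,
                          format = c("csv", "tsv")) {
  format <- match.arg(format)
  combined <- join_results(mentions, classifications)
  if (format == "csv") {
    utils::write.csv(combined, path, row.names = FALSE, na = "")
  } else {
    utils::write.table(combined, path, row.names = FALSE, na = "",
                       sep = "\t", qmethod = "double")
  }
  invisible(combined)
}

join_results <- function(mentions, classifications) {
  mk <- mention_key(mentions)
  ck <- mention_key(classifications)
  orphan <- setdiff(ck, mk)
  if (length(orphan)) {
    stopf("classification without a matching mention: %s",
          paste(utils::head(gsub("\r", ":", orphan), 5), collapse = ", "))
  }
  idx <- match(ck, mk)
  out <- cbind(mentions[idx, setdiff(names(mentions), "label"), drop = FALSE],
               classifications[, c("label", "confidence", "window_used"),
                               drop = FALSE])
  rownames(out) <- NULL
  out[, .result_cols]
}

#' Read a results table written by [write_results()]
#'
#' @inheritParams write_results
#' @return data.frame with the standard result columns.
#' @export
read_results <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  } else {
    utils::read.delim(path, colClasses = "character", encoding = "UTF-8")
  }
  for (f in .result_cols) {
    if (is.null(df[[f]])) stopf("results file is missing column '%s'", f)
  }
  for (f in c("sentence_index", "match_start", "match_end", "context_start")) {
    df[[f]] <- as.integer(df[[f]])
  }
  df$confidence <- as.numeric(df$confidence)
  df$window_used <- suppressWarnings(as.integer(df$window_used))
  df
}
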