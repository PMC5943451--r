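# Sentence splitting, tokenization, POS tagging and per-document annotation.
# All spans are 0-based half-open character intervals into the document text.

#' Split document text into sentences
#'
#' Rule-based splitter for clinical notes: sentence boundaries fall after runs
#' of terminal punctuation (`.` `!` `?` `;`) followed by whitespace, and at
#' newline runs. A line without terminal punctuation (a heading such as
#' \dQuote{Past suicide attempts}) therefore forms its own sentence, which the
#' neutral-mention filters rely on.
#'
#' @param text a single character string (may be empty).
#' @return data.frame with columns `index` (0-based ordinal), `start`, `end`
#'   (0-based half-open character span) and `text` (the exact document slice).
#' @examples
#' split_sentences("He denied ideation. She was discharged.")
#' split_sentences("Past suicide attempts\nNone reported")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- data.frame(index = integer(0), start = integer(0), end = integer(0),
                    text = character(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(out)

  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_nl <- chars %in% c("\n", "\r")
  is_ws <- grepl("^[[:space:]]$", chars)
  is_term <- chars %in% c(".", "!", "?", ";")

  starts <- integer(0); ends <- integer(0)
  seg_start <- 1L
  i <- 1L
  flush <- function(a, b) {
    # trim whitespace from both ends; drop empty pieces
    while (a <= b && is_ws[a]) a <- a + 1L
    while (b >= a && is_ws[b]) b <- b - 1L
    if (a <= b) {
      starts <<- c(starts, a - 1L)   # to 0-based
      ends <<- c(ends, b)            # half-open
    }
  }
  while (i <= n) {
    if (is_nl[i]) {
      flush(seg_start, i - 1L)
      while (i <= n && is_nl[i]) i <- i + 1L
      seg_start <- i
    } else if (is_term[i]) {
      j <- i
      while (j < n && is_term[j + 1L]) j <- j + 1L
      if (j == n || is_ws[j + 1L]) {
        flush(seg_start, j)
        seg_start <- j + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  flush(seg_start, n)

  if (!length(starts)) return(out)
  data.frame(index = seq_along(starts) - 1L, start = starts, end = ends,
             text = slice_text(text, starts, ends), stringsAsFactors = FALSE)
}

#' Tokenize text into word and punctuation tokens
#'
#' Tokens are maximal alphanumeric runs plus standalone punctuation
#' characters; whitespace is discarded. Offsets are exact 0-based half-open
#' spans into the enclosing document when `offset` is the text's document
#' offset.
#'
#' @param text a single character string.
#' @param offset 0-based document offset of `text`'s first character.
#' @return data.frame with columns `start`, `end`, `surface`.
#' @examples
#' tokenize("E950-959")
#' tokenize("wants to die")
#' @export
tokenize <- function(text, offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- data.frame(start = integer(0), end = integer(0),
                    surface = character(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(out)
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  len <- attr(m, "match.length")
  data.frame(start = offset + m - 1L, end = offset + m - 1L + len,
             surface = substring(text, m, m + len - 1L),
             stringsAsFactors = FALSE)
}

# Small closed-class lexicon for the deterministic Penn-style tagger.
.pos_lexicon <- local({
  lex <- c(
    "i" = "PRP", "he" = "PRP", "she" = "PRP", "it" = "PRP", "we" = "PRP",
    "they" = "PRP", "you" = "PRP", "him" = "PRP", "them" = "PRP",
    "himself" = "PRP", "herself" = "PRP", "themselves" = "PRP",
    "yourself" = "PRP", "me" = "PRP", "us" = "PRP",
    "her" = "PRP$", "his" = "PRP$", "their" = "PRP$", "my" = "PRP$",
    "your" = "PRP$", "our" = "PRP$", "its" = "PRP$",
    "the" = "DT", "a" = "DT", "an" = "DT", "this" = "DT", "that" = "DT",
    "these" = "DT", "those" = "DT", "any" = "DT", "some" = "DT", "no" = "DT",
    "each" = "DT", "every" = "DT",
    "of" = "IN", "in" = "IN", "on" = "IN", "at" = "IN", "by" = "IN",
    "with" = "IN", "from" = "IN", "for" = "IN", "about" = "IN",
    "after" = "IN", "before" = "IN", "under" = "IN", "over" = "IN",
    "during" = "IN", "into" = "IN", "since" = "IN", "without" = "IN",
    "to" = "TO",
    "and" = "CC", "or" = "CC", "but" = "CC", "nor" = "CC",
    "will" = "MD", "would" = "MD", "can" = "MD", "could" = "MD",
    "may" = "MD", "might" = "MD", "shall" = "MD", "should" = "MD",
    "must" = "MD",
    "is" = "VBZ", "was" = "VBD", "are" = "VBP", "were" = "VBD",
    "be" = "VB", "been" = "VBN", "being" = "VBG", "am" = "VBP",
    "has" = "VBZ", "have" = "VBP", "had" = "VBD",
    "does" = "VBZ", "do" = "VBP", "did" = "VBD", "done" = "VBN",
    "says" = "VBZ", "said" = "VBD", "made" = "VBD", "took" = "VBD",
    "taken" = "VBN", "felt" = "VBD", "went" = "VBD", "gave" = "VBD",
    "not" = "RB", "never" = "RB", "ever" = "RB", "currently" = "RB",
    "previously" = "RB", "also" = "RB", "very" = "RB", "there" = "EX",
    "when" = "WRB", "where" = "WRB", "how" = "WRB", "why" = "WRB",
    "who" = "WP", "what" = "WP", "which" = "WDT", "whether" = "IN",
    "if" = "IN", "because" = "IN", "as" = "IN", "than" = "IN",
    "while" = "IN", "although" = "IN", "though" = "IN", "however" = "RB")
  lex
})

#' Deterministic Penn-style part-of-speech tagging
#'
#' A lexicon-plus-suffix tagger: closed-class words come from a fixed
#' lexicon, numbers are tagged `CD`, punctuation receives its own surface as
#' tag, and open-class words are tagged by suffix (`-ed` VBD, `-ing` VBG,
#' `-ly` RB, plural `-s` NNS) with `NN` as default. The tagger is
#' deterministic: the same sentence always receives the same tags. Downstream
#' features consume tags only as opaque strings.
#'
#' @param surfaces character vector of token surfaces from one sentence.
#' @return character vector of tags, one per token.
#' @examples
#' pos_tag(c("She", "attempted", "suicide"))
#' @export
pos_tag <- function(surfaces) {
  if (!length(surfaces)) return(character(0))
  vapply(as.character(surfaces), function(s) {
    low <- fold_case(s)
    if (!is.na(.pos_lexicon[low])) return(unname(.pos_lexicon[low]))
    if (grepl("^[0-9]+$", s)) return("CD")
    if (grepl("^[[:alnum:]]", s)) {
      if (grepl("[0-9]", s)) return("CD")
      if (nchar(s) > 3L && grepl("ed$", low)) return("VBD")
      if (nchar(s) > 4L && grepl("ing$", low)) return("VBG")
      if (nchar(s) > 3L && grepl("ly$", low)) return("RB")
      if (nchar(s) > 2L && grepl("[^su]s$", low)) return("NNS")
      return("NN")
    }
    s  # punctuation tags as itself
  }, character(1), USE.NAMES = FALSE)
}

#' Annotate raw text with sentences and tokens
#'
#' Runs the sentence splitter and tokenizer, then attaches Porter stems and
#' POS tags to every token.
#'
#' @param text a single character string.
#' @return list with elements `sentences` (see [split_sentences()]) and
#'   `tokens`: data.frame with columns `sentence` (0-based sentence index),
#'   `start`, `end`, `surface`, `stem`, `pos`.
#' @export
annotate_text <- function(text) {
  sents <- split_sentences(text)
  toks <- lapply(seq_len(nrow(sents)), function(i) {
    tk <- tokenize(sents$text[i], offset = sents$start[i])
    if (nrow(tk)) tk$sentence <- sents$index[i]
    tk
  })
  toks <- toks[vapply(toks, nrow, integer(1)) > 0L]
  tokens <- if (length(toks)) do.call(rbind, toks) else
    data.frame(start = integer(0), end = integer(0), surface = character(0),
               sentence = integer(0), stringsAsFactors = FALSE)
  if (nrow(tokens)) {
    tokens$stem <- porter_stem(tokens$surface)
    tokens$pos <- unlist(lapply(split(tokens$surface, tokens$sentence),
                                pos_tag), use.names = FALSE)
  } else {
    tokens$stem <- character(0)
    tokens$pos <- character(0)
  }
  rownames(tokens) <- NULL
  list(sentences = sents,
       tokens = tokens[, c("sentence", "start", "end", "surface", "stem", "pos")])
}

#' Annotate every document of a corpus
#'
#' @param corpus clinical corpus data.frame (see [read_corpus()]).
#' @return named list of [annotate_text()] results, keyed by `doc_id`.
#' @export
annotate_corpus <- function(corpus) {
  ann <- lapply(corpus$text, annotate_text)
  names(ann) <- corpus$doc_id
  ann
}

#' Stop-word lists
#'
#' `read_stopwords()` reads a plain-text list, one lowercase token per line
#' (`#` comment lines allowed). `default_stopwords()` returns the packaged
#' English list; the packaged list deliberately excludes negation words
#' (no/not/never/nor) because they carry assertion signal in clinical text.
#'
#' @param path path to a stop-word file.
#' @return character vector of lowercase stop words.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stopf("stop-word file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(fold_case(lines))
}

#' @rdname read_stopwords
#' @export
default_stopwords <- function() {
  read_stopwords(pkg_extdata("stopwords_en.txt"))
}
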