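# Gazetteers: lexicons of (optionally wildcarded) token-sequence patterns
# used for dictionary matching. A trailing "*" on a pattern token matches any
# text token having the rest as a prefix (so "ideat*" matches "ideation" and
# "ideations" but not "idea").

#' Construct a gazetteer
#'
#' @param entries list of character vectors; each vector is one pattern, one
#'   element per token, a token optionally ending in `*` (prefix wildcard).
#'   Entries given as single strings are tokenized on whitespace and then with
#'   the package tokenizer, so patterns align with tokenized text (e.g.
#'   `"didn't"` becomes the three tokens `didn` `'` `t`).
#' @param name gazetteer name.
#' @param case_policy `"fold"` (case-insensitive, the default) or `"exact"`.
#' @return object of class `gazetteer`.
#' @export
gazetteer <- function(entries, name = "gazetteer", case_policy = c("fold", "exact")) {
  case_policy <- match.arg(case_policy)
  entries <- lapply(entries, function(e) {
    if (length(e) == 1L && grepl("[[:space:]]", e)) e <- strsplit(trimws(e), "[[:space:]]+")[[1]]
    unlist(lapply(e, split_pattern_token), use.names = FALSE)
  })
  for (e in entries) {
    if (!length(e)) stopf("empty gazetteer pattern")
    if (any(e == "*")) stopf("lone '*' wildcard in gazetteer pattern")
    if (any(grepl("\\*.", e))) stopf("'*' is only allowed at the end of a pattern token")
  }
  structure(list(name = name, entries = entries, case_policy = case_policy),
            class = "gazetteer")
}

# Re-tokenize one whitespace-delimited pattern piece with the text tokenizer,
# keeping a terminal wildcard attached to the final sub-token.
split_pattern_token <- function(piece) {
  if (piece == "*") return("*")
  wild <- endsWith(piece, "*")
  lit <- if (wild) substr(piece, 1L, nchar(piece) - 1L) else piece
  sub <- tokenize(lit)$surface
  if (!length(sub)) return(if (wild) "*" else character(0))
  if (wild) sub[length(sub)] <- paste0(sub[length(sub)], "*")
  sub
}

#' Read a gazetteer file
#'
#' One pattern per line; blank lines and lines starting with `#` are ignored.
#' A directive line `#!case: exact` (or `fold`) before any pattern sets the
#' case policy; the default is case folding.
#'
#' @param path path to a UTF-8 plain-text gazetteer file.
#' @param name gazetteer name; defaults to the file name.
#' @return object of class `gazetteer`.
#' @examples
#' f <- tempfile()
#' writeLines(c("# positives", "suicid* ideat*"), f)
#' read_gazetteer(f)
#' @export
read_gazetteer <- function(path, name = basename(path)) {
  if (!file.exists(path)) stopf("gazetteer file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  case_policy <- "fold"
  dir <- grep("^#!case:", lines)
  if (length(dir)) {
    val <- trimws(sub("^#!case:", "", lines[dir[1]]))
    if (!val %in% c("fold", "exact")) stopf("unknown case policy '%s' in %s", val, path)
    case_policy <- val
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gazetteer(as.list(lines), name = name, case_policy = case_policy)
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer '%s': %d patterns, case %s>\n",
              x$name, length(x$entries), x$case_policy))
  invisible(x)
}

match_one_token <- function(pattern_token, surface) {
  if (endsWith(pattern_token, "*")) {
    startsWith(surface, substr(pattern_token, 1L, nchar(pattern_token) - 1L))
  } else {
    surface == pattern_token
  }
}

#' Match gazetteer patterns against sentence tokens
#'
#' A pattern matches a contiguous run of tokens where each literal pattern
#' token equals the text token (under the gazetteer's case policy) and each
#' wildcard token is a prefix of it. All matches are reported, including
#' overlapping matches of different patterns; exact duplicates (same entry,
#' same span) are collapsed.
#'
#' @param gaz a [gazetteer()].
#' @param surfaces character vector of token surfaces, in sentence order.
#' @return data.frame with columns `entry` (index into `gaz$entries`),
#'   `first`, `last` (1-based token indices of the matched run).
#' @export
match_gazetteer <- function(gaz, surfaces) {
  stopifnot(inherits(gaz, "gazetteer"))
  out <- data.frame(entry = integer(0), first = integer(0), last = integer(0))
  n <- length(surfaces)
  if (!n) return(out)
  txt <- if (gaz$case_policy == "fold") fold_case(surfaces) else as.character(surfaces)
  rows <- list()
  for (e in seq_along(gaz$entries)) {
    pat <- gaz$entries[[e]]
    if (gaz$case_policy == "fold") pat <- fold_case(pat)
    L <- length(pat)
    if (L > n) next
    for (i in seq_len(n - L + 1L)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!match_one_token(pat[j], txt[i + j - 1L])) { ok <- FALSE; break }
      }
      if (ok) rows[[length(rows) + 1L]] <- c(e, i, i + L - 1L)
    }
  }
  if (!length(rows)) return(out)
  m <- do.call(rbind, rows)
  out <- unique(data.frame(entry = m[, 1], first = m[, 2], last = m[, 3]))
  rownames(out) <- NULL
  out
}
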