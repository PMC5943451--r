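# Porter (1980) suffix-stripping stemmer, implemented from the published
# algorithm: steps 1a-5b over the measure m of the [C](VC)^m[V] decomposition.

porter_cons <- function(ch) {
  n <- length(ch)
  v <- logical(n)
  for (i in seq_len(n)) {
    c <- ch[i]
    v[i] <- if (c %in% c("a", "e", "i", "o", "u")) FALSE
    else if (c == "y") (if (i == 1L) TRUE else !v[i - 1L])
    else TRUE
  }
  v
}

porter_measure <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (length(ch) < 2L) return(0L)
  cons <- porter_cons(ch)
  sum(!cons[-length(cons)] & cons[-1L])
}

porter_has_vowel <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (!length(ch)) return(FALSE)
  any(!porter_cons(ch))
}

porter_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L); b <- substr(w, n, n)
  if (a != b) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  porter_cons(ch)[n]
}

# *o: stem ends cvc where the final consonant is not w, x or y.
porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  cons <- porter_cons(ch)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(ch[n] %in% c("w", "x", "y"))
}

porter_ends <- function(w, s) {
  n <- nchar(w); k <- nchar(s)
  n > k && substr(w, n - k + 1L, n) == s
}

porter_chop <- function(w, s) substr(w, 1L, nchar(w) - nchar(s))

# Apply the first (longest) matching suffix rule of a step-2/3/4 style table;
# once a suffix matches, the step is consumed whether or not the m-condition
# holds, per the reference algorithm.
porter_rule_table <- function(w, table, m_min) {
  sufs <- names(table)
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (s in sufs) {
    if (porter_ends(w, s)) {
      stem <- porter_chop(w, s)
      if (porter_measure(stem) > m_min) w <- paste0(stem, table[[s]])
      return(w)
    }
  }
  w
}

porter_stem_one <- function(word) {
  w <- fold_case(word)
  if (nchar(w) <= 2L || !grepl("^[a-z]+$", w)) return(w)

  # Step 1a
  if (porter_ends(w, "sses")) w <- paste0(porter_chop(w, "sses"), "ss")
  else if (porter_ends(w, "ies")) w <- paste0(porter_chop(w, "ies"), "i")
  else if (!porter_ends(w, "ss") && porter_ends(w, "s")) w <- porter_chop(w, "s")

  # Step 1b
  if (porter_ends(w, "eed")) {
    if (porter_measure(porter_chop(w, "eed")) > 0L) w <- porter_chop(w, "d")
  } else {
    stripped <- FALSE
    if (porter_ends(w, "ed") && porter_has_vowel(porter_chop(w, "ed"))) {
      w <- porter_chop(w, "ed"); stripped <- TRUE
    } else if (porter_ends(w, "ing") && porter_has_vowel(porter_chop(w, "ing"))) {
      w <- porter_chop(w, "ing"); stripped <- TRUE
    }
    if (stripped) {
      if (porter_ends(w, "at") || porter_ends(w, "bl") || porter_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (porter_double_cons(w) && !grepl("[lsz]$", w)) {
        w <- substr(w, 1L, nchar(w) - 1L)
      } else if (porter_measure(w) == 1L && porter_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # Step 1c
  if (porter_ends(w, "y") && porter_has_vowel(porter_chop(w, "y"))) {
    w <- paste0(porter_chop(w, "y"), "i")
  }

  # Step 2
  w <- porter_rule_table(w, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"), 0L)

  # Step 3
  w <- porter_rule_table(w, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""), 0L)

  # Step 4 ("ion" only after s or t)
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ion", "ism",
            "ate", "iti", "ous", "ive", "ize", "ant", "ent", "al", "er",
            "ic", "ou")
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (s in sufs) {
    if (porter_ends(w, s)) {
      stem <- porter_chop(w, s)
      ok <- porter_measure(stem) > 1L
      if (s == "ion") ok <- ok && grepl("[st]$", stem)
      if (ok) w <- stem
      break
    }
  }

  # Step 5a
  if (porter_ends(w, "e")) {
    stem <- porter_chop(w, "e")
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) w <- stem
  }

  # Step 5b
  if (porter_measure(w) > 1L && porter_double_cons(w) && grepl("l$", w)) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  w
}

#' Porter stem of a token surface
#'
#' Deterministic suffix-stripping stem (Porter 1980), case-folded. Tokens
#' shorter than three characters or containing non-letters are returned
#' case-folded but otherwise untouched.
#'
#' @param x character vector of token surfaces.
#' @return character vector of stems, same length as `x`.
#' @examples
#' porter_stem(c("attempted", "ideation", "ideations", "suicidal"))
#' @export
porter_stem <- function(x) {
  vapply(as.character(x), porter_stem_one, character(1), USE.NAMES = FALSE)
}
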