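# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "suicidenlp_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Character offsets are 0-based half-open throughout the package; this is the
# one place the convention is converted to R's 1-based substring().
slice_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

fold_case <- function(x) tolower(x)

mention_key <- function(df) {
  paste(df$doc_id, df$match_start, df$match_end, sep = "\r")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

empty_mentions <- function() {
  data.frame(doc_id = character(0), patient_id = character(0),
             concept = character(0), sentence_index = integer(0),
             match = character(0), match_start = integer(0),
             match_end = integer(0), context_string = character(0),
             context_start = integer(0), stringsAsFactors = FALSE)
}

empty_classifications <- function() {
  data.frame(doc_id = character(0), match_start = integer(0),
             match_end = integer(0), label = character(0),
             confidence = numeric(0), window_used = integer(0),
             stringsAsFactors = FALSE)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "suicidenlp")
  if (!nzchar(path)) stopf("packaged data file '%s' not found", file)
  path
}
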