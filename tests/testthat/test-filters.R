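as_true_classifications <- function(mentions) {
  data.frame(doc_id = mentions$doc_id, match_start = mentions$match_start,
             match_end = mentions$match_end, label = "true_event",
             confidence = 0.9, window_used = 1L, stringsAsFactors = FALSE)
}

test_that("the packaged rulebook vetoes titles, ambiguity and pre-match negation", {
  corpus <- tiny_corpus(c(
    "Have you ever attempted suicide?",
    "the note said previously also attempted to suicide attempt context",
    "she would not attempt to take her life",
    "b) Suicide attempts x",
    "Suicide attempts/ideation",
    "History of previous suicide attempts",
    "made a serious suicide attempt by hanging"))
  mentions <- detect_attempt_mentions(corpus)
  cls <- as_true_classifications(mentions)
  res <- apply_filters(cls, mentions)

  by_doc <- function(d) res$classifications$label[res$classifications$doc_id == d]
  expect_true(all(by_doc("d001") == "non_true_event"))
  expect_true(all(by_doc("d002") == "non_true_event"))
  expect_true(all(by_doc("d003") == "non_true_event"))
  expect_true(all(by_doc("d004") == "non_true_event"))
  expect_true(all(by_doc("d005") == "non_true_event"))
  expect_true(all(by_doc("d006") == "non_true_event"))
  # a narrative clause survives every rule
  expect_true(all(by_doc("d007") == "true_event"))

  cat_of <- function(d) unique(res$log$category[res$log$doc_id == d])
  expect_equal(cat_of("d001"), "title_neutral")
  expect_true("ambiguous" %in% cat_of("d002"))
  expect_equal(cat_of("d003"), "negation_before_match")
  expect_equal(cat_of("d004"), "title_neutral")
  expect_equal(cat_of("d005"), "title_neutral")
  expect_equal(cat_of("d006"), "title_neutral")
})

test_that("a heading near a narrative mention does not veto the narrative", {
  corpus <- tiny_corpus(paste(
    "Past suicide attempts",
    "Have you ever attempted suicide?",
    "She took an overdose of 20 paracetamol tablets in a suicide attempt.",
    sep = "\n"))
  mentions <- detect_attempt_mentions(corpus)
  res <- apply_filters(as_true_classifications(mentions), mentions)
  labels <- res$classifications$label[order(mentions$sentence_index)]
  by_sent <- split(res$classifications$label, mentions$sentence_index)
  expect_true(all(by_sent[["0"]] == "non_true_event"))  # heading line
  expect_true(all(by_sent[["1"]] == "non_true_event"))  # questionnaire line
  expect_true(all(by_sent[["2"]] == "true_event"))      # narrative survives
})

test_that("filters only flip positives, never resurrect, and are idempotent", {
  gen <- generate_corpus(synthetic_config(n_docs = 120, seed = 31))
  mentions <- detect_attempt_mentions(gen$corpus)
  cls <- as_true_classifications(mentions)
  cls$label[seq(1, nrow(cls), by = 3)] <- "non_true_event"

  once <- apply_filters(cls, mentions)
  # direction: no non_true_event ever becomes true_event
  flipped_up <- cls$label == "non_true_event" &
    once$classifications$label == "true_event"
  expect_false(any(flipped_up))
  expect_lte(sum(once$classifications$label == "true_event"),
             sum(cls$label == "true_event"))
  # idempotence
  twice <- apply_filters(once$classifications, mentions)
  expect_identical(twice$classifications, once$classifications)
  expect_equal(nrow(twice$log), 0L)
  # log rows correspond exactly to the flipped instances
  expect_equal(nrow(once$log),
               sum(cls$label == "true_event" &
                     once$classifications$label == "non_true_event"))
})

test_that("custom rulebooks are validated", {
  f <- withr::local_tempfile()
  writeLines(c("rule_id\tfield\tpattern\tcategory",
               "r1\tmatch\t(unclosed\ttitle_neutral"), f)
  expect_error(read_rulebook(f), "invalid pattern")
  f2 <- withr::local_tempfile()
  writeLines(c("rule_id\tfield\tpattern\tcategory",
               "r1\tbody\tx\ttitle_neutral"), f2)
  expect_error(read_rulebook(f2), "field")
  rb <- default_rulebook()
  expect_false(anyDuplicated(rb$rules$rule_id) > 0)
})
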