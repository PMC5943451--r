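test_that("JSONL corpus reading parses both document types and empty files", {
  f <- withr::local_tempfile()
  writeLines(c(
    '{"doc_id":"e1","patient_id":"p1","doc_type":"event","text":"Seen today."}',
    '{"doc_id":"c1","patient_id":"p1","doc_type":"correspondence","text":"Dear colleague","date":"2016-03-01"}'),
    f)
  corpus <- read_corpus(f)
  expect_equal(nrow(corpus), 2L)
  expect_setequal(corpus$doc_type, c("event", "correspondence"))
  expect_equal(corpus$date, c(NA, "2016-03-01"))

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_equal(nrow(read_corpus(empty)), 0L)
})

test_that("schema violations are reported with field and record number", {
  f <- withr::local_tempfile()
  writeLines('{"doc_id":"e1","doc_type":"event","text":"x"}', f)
  expect_error(read_corpus(f), "record 1.*patient_id")

  g <- withr::local_tempfile()
  writeLines('{"doc_id":"e1","patient_id":"p1","doc_type":"letter","text":"x"}', g)
  expect_error(read_corpus(g), "doc_type")

  h <- withr::local_tempfile()
  writeLines(c(
    '{"doc_id":"e1","patient_id":"p1","doc_type":"event","text":"x"}',
    '{"doc_id":"e1","patient_id":"p2","doc_type":"event","text":"y"}'), h)
  expect_error(read_corpus(h), "duplicate doc_id")
})

test_that("write/read round-trips preserve all fields in both formats", {
  corpus <- data.frame(
    doc_id = c("a", "b"), patient_id = c("p1", "p2"),
    doc_type = c("event", "correspondence"),
    text = c("Line one\nPast suicide attempts\nline three", ""),
    date = c("2015-01-02", NA), stringsAsFactors = FALSE)
  for (fmt in c("jsonl", "csv")) {
    f <- withr::local_tempfile()
    write_corpus(corpus, f, format = fmt)
    back <- read_corpus(f, format = fmt)
    expect_identical(back, corpus, label = fmt)
  }
})

test_that("results tables carry the required columns and round-trip", {
  corpus <- tiny_corpus("She took an overdose in a suicide attempt yesterday.")
  mentions <- detect_attempt_mentions(corpus)
  expect_gt(nrow(mentions), 0L)
  cls <- data.frame(doc_id = mentions$doc_id, match_start = mentions$match_start,
                    match_end = mentions$match_end, label = "true_event",
                    confidence = 0.9, window_used = 1L, stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  combined <- write_results(mentions, cls, f)
  expect_true(all(c("doc_id", "patient_id", "concept", "match",
                    "context_string", "label", "confidence") %in% names(combined)))
  back <- read_results(f)
  expect_equal(back$match, combined$match)
  expect_equal(back$context_string, combined$context_string)
  expect_equal(back$confidence, combined$confidence)

  orphan <- cls
  orphan$match_start <- orphan$match_start + 999L
  expect_error(write_results(mentions, orphan, f), "without a matching mention")
})

test_that("context excerpts honor the character budget and stay centred", {
  long <- paste(rep("this line is filler text for the surrounding note", 30),
                collapse = "\n")
  text <- paste(long, "she attempted suicide by overdose", long, sep = "\n")
  corpus <- tiny_corpus(text)
  mentions <- detect_attempt_mentions(corpus)
  expect_true(all(nchar(mentions$context_string) <= 500L))
  expect_true(all(grepl("attempted suicide", mentions$context_string)))
  # a one-sentence document longer than the budget is hard-truncated
  word <- paste(rep("word", 300), collapse = " ")
  corpus2 <- tiny_corpus(paste(word, "suicide attempt", word))
  m2 <- detect_attempt_mentions(corpus2)
  expect_true(all(nchar(m2$context_string) <= 500L))
  expect_true(all(grepl("suicide attempt", m2$context_string)))
  # the slice bookkeeping is exact
  rel <- m2$match_start - m2$context_start + 1L
  expect_equal(substr(m2$context_string, rel, rel + nchar(m2$match) - 1L),
               m2$match)
})
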