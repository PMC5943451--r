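test_that("dictionary matching emits one mention per hit, filtering deferred", {
  corpus <- tiny_corpus(c(
    "took an overdose in a suicide attempt",
    "History of previous suicide attempts",
    "seen at the clinic for routine review"))
  m <- detect_attempt_mentions(corpus)
  expect_equal(sum(m$doc_id == "d001"), 2L)  # "overdose" + "suicide attempt"
  expect_equal(sum(m$doc_id == "d002"), 1L)
  expect_equal(sum(m$doc_id == "d003"), 0L)
  expect_true(all(m$concept == "attempt"))
  # match text is the exact document slice
  expect_identical(substring(corpus$text[match(m$doc_id, corpus$doc_id)],
                             m$match_start + 1L, m$match_end), m$match)
})

test_that("context windows clip at document edges and deduplicate", {
  w_mid <- build_windows(2L, 5L)
  expect_equal(nrow(w_mid), 6L)
  expect_equal(w_mid$first, c(2L, 1L, 2L, 1L, 0L, 2L))
  expect_equal(w_mid$last, c(2L, 2L, 3L, 3L, 2L, 4L))

  w_single <- build_windows(0L, 1L)
  expect_equal(nrow(w_single), 1L)
  expect_equal(w_single$id, 1L)

  # first sentence of a long document: the three backward-looking specs all
  # clip onto already-present windows
  w_first <- build_windows(0L, 10L)
  expect_equal(nrow(w_first), 3L)
  expect_equal(w_first[, c("first", "last")],
               data.frame(first = c(0L, 0L, 0L), last = c(0L, 1L, 2L)),
               ignore_attr = TRUE)
  # every window contains the concept sentence
  expect_true(all(w_first$first <= 0L & w_first$last >= 0L))
})

test_that("feature extraction counts stems and honors stop words and flags", {
  ann <- annotate_text("she attempted it")
  fv <- extract_features(ann$tokens)
  expect_equal(unname(fv["s:she"]), 1)
  expect_equal(unname(fv["s:attempt"]), 1)
  expect_equal(unname(fv["s:it"]), 1)
  expect_true(any(startsWith(names(fv), "sp:attempt/")))
  expect_false(any(startsWith(names(fv), "ctx:")))

  fv_sw <- extract_features(ann$tokens, stopwords = default_stopwords())
  expect_false(any(c("s:she", "s:it") %in% names(fv_sw)))
  expect_true("s:attempt" %in% names(fv_sw))

  flags <- list(negated = TRUE, historical = FALSE, experiencer_other = FALSE)
  fv_fl <- extract_features(ann$tokens, flags)
  expect_equal(unname(fv_fl["ctx:negated"]), 1)
  expect_identical(extract_features(ann$tokens, flags),
                   extract_features(ann$tokens, flags))
  expect_true(all(fv_fl >= 1))
})

test_that("degenerate training inputs raise informative errors", {
  d <- planted_keyword_corpus(1, n = 40)
  mentions <- detect_attempt_mentions(d$corpus)
  lab <- d$labels[match(mentions$doc_id, d$corpus$doc_id)]
  expect_error(attempt_model(d$corpus, mentions, rep("true_event", nrow(mentions))),
               "single class")
  expect_error(attempt_config(cost_grid = numeric(0)), "empty model grid")
  expect_error(attempt_model(d$corpus, mentions, lab[-1]), "one label per mention")
})

test_that("model selection is invariant to duplicating every instance at fixed folds", {
  d <- planted_keyword_corpus(3, n = 60)
  mentions <- detect_attempt_mentions(d$corpus)
  lab <- d$labels[match(mentions$doc_id, d$corpus$doc_id)]
  fold <- rep_len(1:5, nrow(mentions))
  m1 <- attempt_model(d$corpus, mentions, lab, seed = 1, folds = fold)

  dup_corpus <- d$corpus
  dup_corpus$doc_id <- paste0(dup_corpus$doc_id, "x")
  corpus2 <- rbind(d$corpus, dup_corpus)
  mentions2 <- rbind(mentions, transform(mentions, doc_id = paste0(doc_id, "x")))
  m2 <- attempt_model(corpus2, mentions2, c(lab, lab), seed = 1,
                      folds = c(fold, fold))
  expect_identical(m1$selected, m2$selected)
})

test_that("fits are reproducible and survive serialization bit-identically", {
  d <- planted_keyword_corpus(5, n = 80)
  mentions <- detect_attempt_mentions(d$corpus)
  lab <- d$labels[match(mentions$doc_id, d$corpus$doc_id)]
  m1 <- attempt_model(d$corpus, mentions, lab, seed = 9)
  m2 <- attempt_model(d$corpus, mentions, lab, seed = 9)
  expect_identical(m1$fingerprint, m2$fingerprint)
  expect_identical(predict(m1, d$corpus, mentions), predict(m2, d$corpus, mentions))

  f <- withr::local_tempfile()
  write_model(m1, f)
  m3 <- read_model(f)
  expect_identical(m3$fingerprint, m1$fingerprint)
  expect_identical(predict(m3, d$corpus, mentions), predict(m1, d$corpus, mentions))
})

test_that("classification picks the most confident window and tolerates unseen text", {
  d <- planted_keyword_corpus(7, n = 80)
  mentions <- detect_attempt_mentions(d$corpus)
  lab <- d$labels[match(mentions$doc_id, d$corpus$doc_id)]
  m <- attempt_model(d$corpus, mentions, lab, seed = 2)

  cls <- predict(m, d$corpus, mentions)
  expect_true(all(cls$label %in% c("true_event", "non_true_event")))
  expect_true(all(cls$confidence >= 0 & cls$confidence <= 1))
  expect_true(all(cls$window_used %in% 1:6))
  expect_gt(f1_of(lab, cls$label), 0.95)

  # unseen-vocabulary mention: label comes from the bias, no error
  alien <- tiny_corpus("zzzz qqqq suicide attempt wwww vvvv")
  am <- detect_attempt_mentions(alien)
  acls <- predict(m, alien, am)
  expect_equal(nrow(acls), 1L)
  expect_true(acls$confidence >= 0 && acls$confidence <= 1)

  # an affirmed narrative from the generator classifies positive
  gen <- generate_corpus(synthetic_config(n_docs = 120, seed = 21))
  gm <- detect_attempt_mentions(gen$corpus)
  gl <- align_gold(gm, gen$gold)
  keep <- !is.na(gl)
  mg <- attempt_model(gen$corpus, gm[keep, ], gl[keep], seed = 3)
  aff <- mention_categories(gm, gen$manifest) == "affirmed_attempt"
  aff[is.na(aff)] <- FALSE
  gcls <- predict(mg, gen$corpus, gm[aff, ])
  expect_gt(mean(gcls$label == "true_event" & gcls$confidence > 0.5), 0.9)
})

test_that("review ranking returns the lowest-confidence instances, stably", {
  cls <- data.frame(doc_id = c("a", "b", "c", "d"),
                    match_start = 0L, match_end = 1L,
                    label = "true_event",
                    confidence = c(0.9, 0.51, 0.99, 0.51),
                    window_used = 1L, stringsAsFactors = FALSE)
  expect_equal(rank_for_review(cls, 1)$doc_id, "b")
  expect_equal(rank_for_review(cls, 2)$doc_id, c("b", "d"))  # stable tie
  expect_equal(nrow(rank_for_review(cls, 0)), 0L)
  expect_equal(nrow(rank_for_review(cls, 10)), 4L)
})
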