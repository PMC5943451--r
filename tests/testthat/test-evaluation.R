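test_that("confusion counts follow the classifier-rows/gold-columns layout", {
  all_pos <- rep("true_event", 10)
  cm <- confusion(all_pos, all_pos)
  expect_equal(c(cm$a, cm$b, cm$c, cm$d), c(10L, 0L, 0L, 0L))

  gold <- c(rep("true_event", 4), rep("non_true_event", 6))
  inv <- ifelse(gold == "true_event", "non_true_event", "true_event")
  cm2 <- confusion(gold, inv)
  expect_equal(cm2$a, 0L)
  expect_equal(cm2$d, 0L)
  expect_equal(cm2$b, 4L)
  expect_equal(cm2$c, 6L)

  expect_error(confusion(c(k1 = "true_event"), c(k2 = "true_event")),
               "orphans")
})

test_that("fixture labels reproduce the published evaluation tables", {
  fx1 <- make_gold_fixture(confusion_matrix(265, 37, 24, 174), seed = 1)
  cm1 <- confusion(fx1$gold, fx1$pred)
  expect_equal(c(cm1$a, cm1$b, cm1$c, cm1$d), c(265L, 37L, 24L, 174L))

  fx2 <- make_gold_fixture(confusion_matrix(381, 7, 79, 33), seed = 1)
  cm2 <- confusion(fx2$gold, fx2$pred)
  expect_equal(c(cm2$a, cm2$b, cm2$c, cm2$d), c(381L, 7L, 79L, 33L))

  fx3 <- make_gold_fixture(confusion_matrix(1, 0, 0, 0), seed = 1)
  expect_equal(fx3$gold$label, "true_event")
  expect_equal(fx3$pred$label, "true_event")
})

test_that("precision/recall use exact arithmetic with undefined markers", {
  rep1 <- precision_recall(confusion_matrix(265, 37, 24, 174))
  expect_equal(rep1$precision, 265 / 289)
  expect_equal(rep1$recall, 265 / 302)
  expect_equal(pct(rep1$precision), 91.7)
  expect_equal(pct(rep1$recall), 87.7)

  rep2 <- precision_recall(confusion_matrix(381, 7, 79, 33))
  expect_equal(pct(rep2$precision), 82.8)
  expect_equal(pct(rep2$recall), 98.2)

  rep0 <- precision_recall(confusion_matrix(0, 0, 0, 10))
  expect_true(is.na(rep0$precision) && is.na(rep0$recall) && is.na(rep0$f1))
  out <- capture.output(print(rep0))
  expect_true(any(grepl("undefined", out)))
})

test_that("metrics equal a brute-force recount from raw label pairs", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(2:60, 1)
    gold <- sample(c("true_event", "non_true_event"), n, replace = TRUE)
    pred <- sample(c("true_event", "non_true_event"), n, replace = TRUE)
    cm <- confusion(gold, pred)
    expect_equal(cm$a + cm$b + cm$c + cm$d, n)
    rep <- precision_recall(cm)
    want <- prec_rec_of(gold, pred)  # direct recount
    if (!is.nan(want["precision"])) expect_equal(rep$precision, unname(want["precision"]))
    if (!is.nan(want["recall"])) expect_equal(rep$recall, unname(want["recall"]))
  }
})

test_that("Cohen's kappa matches hand computation and behaves at the limits", {
  v <- rep(c("y", "n"), 50)
  expect_equal(cohens_kappa(v, v), 1)

  r1 <- rep(c("y", "y", "n", "n"), c(40, 10, 10, 40))
  r2 <- rep(c("y", "n", "y", "n"), c(40, 10, 10, 40))
  expect_equal(cohens_kappa(r1, r2), 0.6)  # p_o = 0.8, p_e = 0.5

  # label-name swap applied to both raters leaves kappa unchanged
  sw <- function(x) ifelse(x == "y", "n", "y")
  expect_equal(cohens_kappa(sw(r1), sw(r2)), cohens_kappa(r1, r2))

  # both raters constant and identical -> 1; constant but disjoint raters
  # have p_o = p_e = 0, hence kappa 0
  expect_equal(cohens_kappa(rep("y", 5), rep("y", 5)), 1)
  expect_equal(cohens_kappa(rep("y", 5), rep("n", 5)), 0)

  set.seed(77)
  a <- sample(c("y", "n"), 10000, replace = TRUE)
  b <- sample(c("y", "n"), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
})

test_that("pairwise kappa reports the pair set plus mean for 3+ annotators", {
  set.seed(5)
  base <- sample(c("y", "n"), 200, replace = TRUE)
  flip <- function(x, p) ifelse(runif(length(x)) < p, ifelse(x == "y", "n", "y"), x)
  lab <- data.frame(r1 = base, r2 = flip(base, 0.1), r3 = flip(base, 0.2))
  kp <- kappa_pairwise(lab)
  expect_equal(nrow(kp$pairs), 3L)
  expect_equal(kp$mean, mean(kp$pairs$kappa))
  expect_equal(kp$pairs$kappa[1], cohens_kappa(lab$r1, lab$r2))
})

test_that("patient rollup flags patients with any surviving positive", {
  cls <- data.frame(
    doc_id = c("a", "b", "c", "d"), match_start = 0L, match_end = 1L,
    label = c("non_true_event", "true_event", "non_true_event", "non_true_event"),
    confidence = 1, window_used = NA_integer_,
    patient_id = c("p1", "p1", "p1", "p2"), stringsAsFactors = FALSE)
  out <- patient_rollup(cls)
  expect_equal(out$ever_event[out$patient_id == "p1"], TRUE)
  expect_equal(out$ever_event[out$patient_id == "p2"], FALSE)
  expect_equal(nrow(patient_rollup(cls[0, ])), 0L)
})
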