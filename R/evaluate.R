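# Evaluation harness: confusion counts a/b/c/d (classifier rows, gold
# columns), precision = a/(a+c), recall = a/(a+b), F1, Cohen's kappa, and the
# per-patient ever-event rollup. Metrics are kept as exact proportions
# internally; display rounds to one decimal in percent.

#' Confusion-count container
#'
#' @param a classifier-true and gold-true count (true positives).
#' @param b classifier-false and gold-true count (false negatives).
#' @param c classifier-true and gold-false count (false positives).
#' @param d classifier-false and gold-false count (true negatives).
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(a, b, c, d) {
  for (x in list(a, b, c, d)) if (!is_count(x)) stopf("counts must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2,
              dimnames = list(classifier = c("true_event", "non_true_event"),
                              gold = c("true_event", "non_true_event")))
  print(m)
  invisible(x)
}

as_label_vector <- function(x, arg) {
  if (is.data.frame(x)) {
    if (is.null(x$key) || is.null(x$label)) {
      stopf("%s data.frame needs columns 'key' and 'label'", arg)
    }
    stats::setNames(as.character(x$label), as.character(x$key))
  } else {
    v <- as.character(x)
    names(v) <- names(x)
    v
  }
}

#' Confusion counts from aligned gold and predicted labels
#'
#' Inputs are named character vectors (names are instance keys) or
#' data.frames with `key` and `label` columns; labels are `true_event` /
#' `non_true_event`. Keys must align one-to-one.
#'
#' @param gold gold-standard labels.
#' @param pred classifier labels.
#' @return a [confusion_matrix()].
#' @export
confusion <- function(gold, pred) {
  g <- as_label_vector(gold, "gold")
  p <- as_label_vector(pred, "pred")
  if (!is.null(names(g)) && !is.null(names(p))) {
    only_g <- setdiff(names(g), names(p))
    only_p <- setdiff(names(p), names(g))
    if (length(only_g) || length(only_p)) {
      stopf("gold/prediction keys do not align; orphans: %s",
            paste(utils::head(c(only_g, only_p), 5), collapse = ", "))
    }
    p <- p[names(g)]
  } else if (length(g) != length(p)) {
    stopf("gold and prediction lengths differ (%d vs %d)", length(g), length(p))
  }
  pos <- "true_event"
  confusion_matrix(a = sum(p == pos & g == pos),
                   b = sum(p != pos & g == pos),
                   c = sum(p == pos & g != pos),
                   d = sum(p != pos & g != pos))
}

#' Precision, recall and F1 from confusion counts
#'
#' Zero denominators give `NA` (undefined-marked), never an error.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `eval_report`: list with `cm`, `precision`,
#'   `recall`, `f1`, `n`.
#' @examples
#' precision_recall(confusion_matrix(265, 37, 24, 174))
#' @export
precision_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  precision <- if (cm$a + cm$c > 0) cm$a / (cm$a + cm$c) else NA_real_
  recall <- if (cm$a + cm$b > 0) cm$a / (cm$a + cm$b) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(cm = cm, precision = precision, recall = recall, f1 = f1,
                 n = cm$a + cm$b + cm$c + cm$d),
            class = "eval_report")
}

#' Display rounding to one decimal in percent
#'
#' @param x proportion in `[0, 1]` (or NA).
#' @return numeric percentage rounded to one decimal, e.g. `91.7`.
#' @export
pct <- function(x) round(100 * x, 1)

#' @export
print.eval_report <- function(x, ...) {
  print(x$cm)
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", pct(v))
  cat(sprintf("n = %d instances\n", x$n))
  cat(sprintf("Precision (PPV) (a/a+c): %s\n", fmt(x$precision)))
  cat(sprintf("Recall (Sensitivity) (a/a+b): %s\n", fmt(x$recall)))
  cat(sprintf("F1: %s\n", fmt(x$f1)))
  invisible(x)
}

#' Cohen's kappa between two annotators
#'
#' kappa = (p_o - p_e) / (1 - p_e) with chance agreement p_e from the product
#' of the marginals. Two identical constant vectors give 1 (perfect
#' agreement); any other degenerate p_e = 1 case is undefined-marked `NA`.
#'
#' @param r1,r2 aligned label vectors of equal length (any two-level or
#'   multi-level labelling).
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' cohens_kappa(rep(c("y", "n"), c(50, 50)),
#'              rep(c("y", "n", "y", "n"), c(40, 10, 10, 40)))
#' @export
cohens_kappa <- function(r1, r2) {
  r1 <- as.character(r1); r2 <- as.character(r2)
  if (length(r1) != length(r2) || !length(r1)) {
    stopf("rater vectors must be aligned and non-empty")
  }
  if (all(r1 == r2)) return(1)
  lev <- sort(unique(c(r1, r2)))
  t1 <- table(factor(r1, lev)) / length(r1)
  t2 <- table(factor(r2, lev)) / length(r2)
  p_o <- mean(r1 == r2)
  p_e <- sum(as.numeric(t1) * as.numeric(t2))
  if (1 - p_e <= 0) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise Cohen's kappa for three or more annotators
#'
#' The aggregation over more than two annotators is reported as the set of
#' pairwise kappas plus their mean.
#'
#' @param labels matrix or data.frame, one column per annotator, aligned
#'   rows.
#' @return list with `pairs` (data.frame rater1, rater2, kappa) and `mean`.
#' @export
kappa_pairwise <- function(labels) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (ncol(labels) < 2L) stopf("need at least two annotators")
  cmb <- utils::combn(ncol(labels), 2)
  pairs <- data.frame(
    rater1 = colnames(labels)[cmb[1, ]],
    rater2 = colnames(labels)[cmb[2, ]],
    kappa = apply(cmb, 2, function(ix) cohens_kappa(labels[[ix[1]]], labels[[ix[2]]])),
    stringsAsFactors = FALSE)
  list(pairs = pairs, mean = mean(pairs$kappa))
}

#' Per-patient ever-event rollup
#'
#' A patient is flagged iff at least one surviving `true_event` mention is
#' attributed to them; this is the document-to-patient aggregation the
#' classifiers exist to feed.
#'
#' @param classifications classification table.
#' @param mentions mention table supplying `patient_id` (may be omitted if
#'   `classifications` already carries `patient_id`).
#' @return data.frame with `patient_id` and logical `ever_event`.
#' @export
patient_rollup <- function(classifications, mentions = NULL) {
  if (is.null(classifications$patient_id)) {
    if (is.null(mentions)) stopf("mentions needed to supply patient_id")
    idx <- match(mention_key(classifications), mention_key(mentions))
    if (anyNA(idx)) stopf("classification without a matching mention")
    classifications$patient_id <- mentions$patient_id[idx]
  }
  if (!nrow(classifications)) {
    return(data.frame(patient_id = character(0), ever_event = logical(0),
                      stringsAsFactors = FALSE))
  }
  agg <- tapply(classifications$label == "true_event",
                classifications$patient_id, any)
  data.frame(patient_id = names(agg), ever_event = unname(agg),
             stringsAsFactors = FALSE)
}

#' Align generator gold labels to detected mentions
#'
#' Joins a gold table keyed by (doc_id, sentence_index) onto a mention table;
#' mentions in sentences without a gold row get `NA`.
#'
#' @param mentions concept-mention table.
#' @param gold gold table with `doc_id`, `sentence_index`, `label` (and
#'   optionally `category`).
#' @return character vector of gold labels, one per mention.
#' @export
align_gold <- function(mentions, gold) {
  key_m <- paste(mentions$doc_id, mentions$sentence_index, sep = "\r")
  key_g <- paste(gold$doc_id, gold$sentence_index, sep = "\r")
  gold$label[match(key_m, key_g)]
}
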