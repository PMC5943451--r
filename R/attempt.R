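# Hybrid suicide-attempt classifier: dictionary concept extraction, ConText
# assertion features, bag-of-words linear SVM over sentence context windows,
# cross-validated model selection and Platt probability calibration.

#' Packaged suicide-attempt term dictionary
#'
#' Seed lexicon of attempt phrases (wildcarded); replaceable with
#' [read_gazetteer()].
#'
#' @return a [gazetteer()].
#' @export
default_attempt_lexicon <- function() {
  read_gazetteer(pkg_extdata("attempt_terms.txt"), name = "attempt_terms")
}

#' Detect suicide-attempt concept mentions
#'
#' One mention per dictionary match per sentence; filtering of neutral or
#' negated mentions happens downstream (model + post-processing rules).
#'
#' @param corpus clinical corpus data.frame.
#' @param lexicon attempt-term [gazetteer()].
#' @param budget context-excerpt budget in characters.
#' @param annotations optional precomputed [annotate_corpus()] result.
#' @return concept-mention data.frame (`concept == "attempt"`).
#' @export
detect_attempt_mentions <- function(corpus, lexicon = default_attempt_lexicon(),
                                    budget = 500L, annotations = NULL) {
  if (is.null(annotations)) annotations <- annotate_corpus(corpus)
  out <- list()
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus[i, ]
    ann <- annotations[[doc$doc_id]]
    if (!nrow(ann$tokens)) next
    sent_idx <- integer(0); t_first <- integer(0); t_last <- integer(0)
    for (s in unique(ann$tokens$sentence)) {
      toks <- ann$tokens[ann$tokens$sentence == s, , drop = FALSE]
      m <- match_gazetteer(lexicon, toks$surface)
      if (!nrow(m)) next
      m <- unique(m[, c("first", "last")])
      m <- m[order(m$first, m$last), , drop = FALSE]
      sent_idx <- c(sent_idx, rep(s, nrow(m)))
      t_first <- c(t_first, m$first)
      t_last <- c(t_last, m$last)
    }
    out[[length(out) + 1L]] <- make_mentions(doc, ann, "attempt", sent_idx,
                                             t_first, t_last, budget = budget)
  }
  if (!length(out)) return(empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# The six window specs: sentence offsets relative to the concept sentence.
# Every spec includes the concept sentence itself.
.window_specs <- list(0L, c(-1L, 0L), c(0L, 1L), c(-1L, 0L, 1L),
                      c(-2L, -1L, 0L), c(0L, 1L, 2L))

#' Sentence context windows around a mention
#'
#' Builds the up-to-six windows (concept sentence alone, one back, one
#' forward, one either side, two back, two forward); specs referencing
#' nonexistent sentences are clipped and duplicate clipped windows collapsed
#' onto the smallest window id.
#'
#' @param sentence_index 0-based index of the concept sentence.
#' @param n_sentences number of sentences in the document.
#' @return data.frame with columns `id` (1..6), `first`, `last` (0-based
#'   sentence index range).
#' @export
build_windows <- function(sentence_index, n_sentences) {
  stopifnot(sentence_index >= 0L, sentence_index < n_sentences)
  rows <- lapply(seq_along(.window_specs), function(id) {
    idx <- sentence_index + .window_specs[[id]]
    idx <- idx[idx >= 0L & idx < n_sentences]
    data.frame(id = id, first = min(idx), last = max(idx))
  })
  w <- do.call(rbind, rows)
  w[!duplicated(w[, c("first", "last")]), , drop = FALSE]
}

#' Bag-of-words feature vector for a context window
#'
#' Counts Porter stems and stem/POS pairs of the window's tokens, optionally
#' dropping stop words (by folded surface), and appends three binary ConText
#' indicator features for the mention's assertion flags.
#'
#' @param tokens token table rows (from [annotate_text()]) for the window.
#' @param flags [apply_context()] result for the mention (or NULL for none).
#' @param stopwords character vector of stop words, or NULL to disable
#'   removal.
#' @return named numeric vector of feature counts (`s:` stem features,
#'   `sp:` stem/POS features, `ctx:` flag indicators).
#' @export
extract_features <- function(tokens, flags = NULL, stopwords = NULL) {
  surf <- fold_case(tokens$surface)
  keep <- if (is.null(stopwords)) rep(TRUE, length(surf)) else !(surf %in% stopwords)
  stems <- tokens$stem[keep]
  pos <- tokens$pos[keep]
  tab <- c(table(paste0("s:", stems)), table(paste0("sp:", stems, "/", pos)))
  feats <- stats::setNames(as.numeric(tab), names(tab))
  if (!length(stems)) feats <- stats::setNames(numeric(0), character(0))
  if (!is.null(flags)) {
    for (fl in c("negated", "historical", "experiencer_other")) {
      if (isTRUE(flags[[fl]])) feats[paste0("ctx:", fl)] <- 1
    }
  }
  feats
}

# Dense feature matrix over a fixed vocabulary.
feature_matrix <- function(feature_list, vocab) {
  X <- matrix(0, nrow = length(feature_list), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(feature_list)) {
    f <- feature_list[[i]]
    f <- f[names(f) %in% vocab]
    if (length(f)) X[i, names(f)] <- unname(f)
  }
  X
}

#' Configuration for the attempt classifier
#'
#' @param cost_grid SVM cost values explored during model selection.
#' @param stopword_grid logical values: explore stop-word removal on/off.
#' @param folds number of stratified cross-validation folds.
#' @param train_window which window spec (1..6) supplies the training
#'   context; default 1, the concept sentence.
#' @param use_context include the three ConText indicator features?
#' @param context_budget context-excerpt budget in characters.
#' @param stopwords stop-word list used when removal is on.
#' @param trigger_lexicon ConText trigger lexicon.
#' @return object of class `attempt_config`.
#' @export
attempt_config <- function(cost_grid = c(0.1, 1, 10),
                           stopword_grid = c(FALSE, TRUE),
                           folds = 5L,
                           train_window = 1L,
                           use_context = TRUE,
                           context_budget = 500L,
                           stopwords = default_stopwords(),
                           trigger_lexicon = default_trigger_lexicon()) {
  if (!length(cost_grid) || !length(stopword_grid)) stopf("empty model grid")
  stopifnot(train_window %in% 1:6, folds >= 2L)
  structure(list(cost_grid = cost_grid, stopword_grid = stopword_grid,
                 folds = as.integer(folds), train_window = as.integer(train_window),
                 use_context = isTRUE(use_context),
                 context_budget = as.integer(context_budget),
                 stopwords = stopwords, trigger_lexicon = trigger_lexicon),
            class = "attempt_config")
}

# ConText flags for each mention, computed on the concept sentence.
mention_flags <- function(mentions, annotations, lexicon) {
  lapply(seq_len(nrow(mentions)), function(k) {
    ann <- annotations[[mentions$doc_id[k]]]
    toks <- ann$tokens[ann$tokens$sentence == mentions$sentence_index[k], ,
                       drop = FALSE]
    inside <- which(toks$start >= mentions$match_start[k] &
                      toks$end <= mentions$match_end[k])
    if (!length(inside)) return(list(negated = FALSE, historical = FALSE,
                                     experiencer_other = FALSE))
    apply_context(min(inside), max(inside), toks$surface, lexicon)
  })
}

window_tokens <- function(ann, first, last) {
  ann$tokens[ann$tokens$sentence >= first & ann$tokens$sentence <= last, ,
             drop = FALSE]
}

mention_window_features <- function(mentions, annotations, flags, config,
                                    window, stopword_removal) {
  sw <- if (stopword_removal) config$stopwords else NULL
  lapply(seq_len(nrow(mentions)), function(k) {
    ann <- annotations[[mentions$doc_id[k]]]
    w <- build_windows(mentions$sentence_index[k], nrow(ann$sentences))
    row <- w[w$id == window, , drop = FALSE]
    if (!nrow(row)) row <- w[nrow(w), , drop = FALSE]  # clipped-away spec: nearest kept window
    fl <- if (config$use_context) flags[[k]] else NULL
    extract_features(window_tokens(ann, row$first, row$last), fl, sw)
  })
}

f1_score <- function(truth, pred, positive = "true_event") {
  a <- sum(truth == positive & pred == positive)
  c_ <- sum(truth != positive & pred == positive)
  b <- sum(truth == positive & pred != positive)
  if (a == 0) return(0)
  p <- a / (a + c_); r <- a / (a + b)
  2 * p * r / (p + r)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Linear SVM wrapper: fit on dense matrix, return signed decision values
# oriented so positive means "true_event".
svm_fit <- function(X, y, cost) {
  yf <- factor(y, levels = c("non_true_event", "true_event"))
  m <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                  cost = cost, scale = FALSE)
  m
}

svm_decision <- function(m, X) {
  p <- stats::predict(m, X, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "true_event")) 1 else -1
  as.numeric(dv[, 1]) * sgn
}

# Platt (1999) sigmoid calibration with regularized targets, fitted on
# out-of-fold decision values; deterministic.
platt_fit <- function(dv, y, positive = "true_event") {
  t_pos <- (sum(y == positive) + 1) / (sum(y == positive) + 2)
  t_neg <- 1 / (sum(y != positive) + 2)
  target <- ifelse(y == positive, t_pos, t_neg)
  nll <- function(par) {
    z <- par[1] * dv + par[2]
    p <- 1 / (1 + exp(z))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(target * log(p) + (1 - target) * log(1 - p))
  }
  init <- c(A = -1, B = log((sum(y != positive) + 1) / (sum(y == positive) + 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  c(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

platt_prob <- function(platt, dv) {
  1 / (1 + exp(platt[["A"]] * dv + platt[["B"]]))
}

#' Fit the hybrid suicide-attempt classification model
#'
#' The fitting function of the package. Explores a grid of stop-word removal
#' on/off by SVM cost, scores each cell by stratified cross-validated F1 on
#' the training mentions, refits the best cell on all data, and fits a Platt
#' sigmoid on the winning cell's out-of-fold decision values so predictions
#' carry a calibrated probability of being correct. Deterministic for a fixed
#' seed, corpus and configuration.
#'
#' @param corpus clinical corpus containing the training documents.
#' @param mentions attempt mentions (see [detect_attempt_mentions()]).
#' @param labels character vector, one of `"true_event"`/`"non_true_event"`
#'   per mention.
#' @param config an [attempt_config()].
#' @param seed integer seed controlling fold assignment.
#' @param folds optional explicit fold assignment vector (overrides seeded
#'   stratified folds).
#' @return object of class `attempt_model`, with components `svm`, `vocab`,
#'   `platt`, `selected` (winning grid cell), `cv_report` (per-cell F1),
#'   `config`, `seed` and a `fingerprint` (digest of weights, vocabulary and
#'   calibration).
#' @export
attempt_model <- function(corpus, mentions, labels, config = attempt_config(),
                          seed = 1L, folds = NULL) {
  stopifnot(inherits(config, "attempt_config"))
  if (nrow(mentions) != length(labels)) stopf("one label per mention required")
  labels <- as.character(labels)
  if (!all(labels %in% c("true_event", "non_true_event"))) {
    stopf("labels must be 'true_event' or 'non_true_event'")
  }
  if (length(unique(labels)) < 2L) stopf("training set contains a single class")

  annotations <- annotate_corpus(corpus[corpus$doc_id %in% mentions$doc_id, ,
                                        drop = FALSE])
  flags <- mention_flags(mentions, annotations, config$trigger_lexicon)

  feats_by_sw <- list()
  for (sw in unique(config$stopword_grid)) {
    feats_by_sw[[as.character(sw)]] <- mention_window_features(
      mentions, annotations, flags, config, config$train_window, sw)
  }

  if (is.null(folds)) {
    fold <- stratified_folds(labels, config$folds, seed)
  } else {
    stopifnot(length(folds) == length(labels))
    fold <- as.integer(folds)
  }
  k <- max(fold)

  grid <- expand.grid(cost = config$cost_grid,
                      stopword_removal = config$stopword_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$f1 <- NA_real_
  oof_store <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    feats <- feats_by_sw[[as.character(grid$stopword_removal[g])]]
    oof_dv <- numeric(length(labels))
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      if (!any(te)) next
      if (length(unique(labels[tr])) < 2L) {
        oof_dv[te] <- if (labels[tr][1] == "true_event") 1 else -1
        next
      }
      vocab <- sort(unique(unlist(lapply(feats[tr], names))))
      if (!length(vocab)) { oof_dv[te] <- 0; next }
      m <- svm_fit(feature_matrix(feats[tr], vocab), labels[tr], grid$cost[g])
      oof_dv[te] <- svm_decision(m, feature_matrix(feats[te], vocab))
    }
    pred <- ifelse(oof_dv > 0, "true_event", "non_true_event")
    grid$f1[g] <- f1_score(labels, pred)
    oof_store[[g]] <- oof_dv
  }

  best <- which.max(grid$f1)  # ties: first cell in grid order
  feats <- feats_by_sw[[as.character(grid$stopword_removal[best])]]
  vocab <- sort(unique(unlist(lapply(feats, names))))
  if (!length(vocab)) stopf("empty training vocabulary")
  X <- feature_matrix(feats, vocab)
  m <- svm_fit(X, labels, grid$cost[best])
  platt <- platt_fit(oof_store[[best]], labels)

  w <- crossprod(m$SV, m$coefs)[, 1]
  sgn <- if (startsWith(colnames(attr(stats::predict(m, X[1, , drop = FALSE],
                                                     decision.values = TRUE),
                                      "decision.values"))[1], "true_event")) 1 else -1
  weights <- sgn * w
  bias <- -sgn * m$rho
  names(weights) <- vocab

  obj <- structure(list(
    svm = m, vocab = vocab, weights = weights, bias = bias, platt = platt,
    selected = list(cost = grid$cost[best],
                    stopword_removal = grid$stopword_removal[best]),
    cv_report = grid, config = config, seed = seed,
    n_train = length(labels), classes = c("non_true_event", "true_event"),
    version = 1L), class = "attempt_model")
  obj$fingerprint <- model_fingerprint(obj)
  obj
}

#' Fingerprint of a fitted attempt model
#'
#' SHA-256 digest of the model's weights, bias, vocabulary, calibration and
#' selected hyper-parameters; identical corpus, config and seed yield an
#' identical fingerprint.
#'
#' @param object an `attempt_model`.
#' @return character scalar.
#' @export
model_fingerprint <- function(object) {
  digest::digest(list(round(unname(object$weights), 10), round(object$bias, 10),
                      object$vocab, round(unname(object$platt), 10),
                      object$selected), algo = "sha256")
}

#' @export
print.attempt_model <- function(x, ...) {
  cat("Hybrid suicide-attempt classifier (linear SVM + Platt calibration)\n")
  cat(sprintf("  training mentions: %d; vocabulary: %d features\n",
              x$n_train, length(x$vocab)))
  cat(sprintf("  selected: cost = %g, stop-word removal = %s (CV F1 = %.3f)\n",
              x$selected$cost, x$selected$stopword_removal,
              max(x$cv_report$f1)))
  cat(sprintf("  fingerprint: %s\n", substr(x$fingerprint, 1, 12)))
  invisible(x)
}

#' @export
summary.attempt_model <- function(object, n = 10L, ...) {
  w <- sort(object$weights, decreasing = TRUE)
  out <- list(cv_report = object$cv_report, selected = object$selected,
              top_positive = utils::head(w, n), top_negative = rev(utils::tail(w, n)),
              platt = object$platt, fingerprint = object$fingerprint)
  class(out) <- "summary.attempt_model"
  out
}

#' @export
print.summary.attempt_model <- function(x, ...) {
  cat("Model-selection grid (cross-validated F1):\n")
  print(x$cv_report, row.names = FALSE)
  cat(sprintf("\nSelected: cost = %g, stop-word removal = %s\n",
              x$selected$cost, x$selected$stopword_removal))
  cat("\nStrongest features toward 'true_event':\n")
  print(round(x$top_positive, 3))
  cat("\nStrongest features toward 'non_true_event':\n")
  print(round(x$top_negative, 3))
  invisible(x)
}

#' @export
coef.attempt_model <- function(object, ...) {
  c("(bias)" = object$bias, object$weights)
}

#' Classify attempt mentions with a fitted model
#'
#' Scores every context window of each mention; the window with the highest
#' calibrated confidence (ties: smallest window id) supplies the label and
#' confidence. Mentions whose window contains no in-vocabulary feature are
#' scored from the model bias alone.
#'
#' @param object a fitted [attempt_model()].
#' @param corpus corpus containing the mentions' documents.
#' @param mentions attempt-mention table to classify.
#' @param annotations optional precomputed annotations.
#' @param ... unused.
#' @return classification data.frame keyed by `doc_id`, `match_start`,
#'   `match_end`, with `label`, `confidence` and `window_used`.
#' @export
predict.attempt_model <- function(object, corpus, mentions,
                                  annotations = NULL, ...) {
  if (!length(object$vocab)) stopf("model vocabulary is empty")
  if (!nrow(mentions)) return(empty_classifications())
  config <- object$config
  if (is.null(annotations)) {
    annotations <- annotate_corpus(corpus[corpus$doc_id %in% mentions$doc_id, ,
                                          drop = FALSE])
  }
  flags <- mention_flags(mentions, annotations, config$trigger_lexicon)
  sw <- if (object$selected$stopword_removal) config$stopwords else NULL

  label <- character(nrow(mentions))
  confidence <- numeric(nrow(mentions))
  window_used <- integer(nrow(mentions))
  for (kk in seq_len(nrow(mentions))) {
    ann <- annotations[[mentions$doc_id[kk]]]
    w <- build_windows(mentions$sentence_index[kk], nrow(ann$sentences))
    fl <- if (config$use_context) flags[[kk]] else NULL
    feats <- lapply(seq_len(nrow(w)), function(j) {
      extract_features(window_tokens(ann, w$first[j], w$last[j]), fl, sw)
    })
    dv <- svm_decision(object$svm, feature_matrix(feats, object$vocab))
    p <- platt_prob(object$platt, dv)
    conf <- pmax(p, 1 - p)
    best <- which.max(conf)          # ties: smallest window id (w is id-ordered)
    label[kk] <- if (p[best] > 0.5) "true_event" else "non_true_event"
    confidence[kk] <- conf[best]
    window_used[kk] <- w$id[best]
  }
  data.frame(doc_id = mentions$doc_id, match_start = mentions$match_start,
             match_end = mentions$match_end, label = label,
             confidence = confidence, window_used = window_used,
             stringsAsFactors = FALSE)
}

#' Lowest-confidence instances for manual review
#'
#' Supports the active-learning loop: reviewing the records the model is
#' least sure about is the cheapest way to grow the gold standard.
#'
#' @param classifications classification table with a `confidence` column.
#' @param n number of instances to return (`n = 0` gives none; `n` larger
#'   than the table returns everything).
#' @return the `n` rows with the lowest confidence, ascending, stable for
#'   ties.
#' @export
rank_for_review <- function(classifications, n) {
  stopifnot(is_count(n))
  ord <- order(classifications$confidence)  # stable
  out <- classifications[utils::head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persist and reload a fitted attempt model
#'
#' The model file is a versioned serialized object with the configuration
#' embedded; `read_model()` checks the version and recomputes the
#' fingerprint.
#'
#' @param object an `attempt_model`.
#' @param path file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   model.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "attempt_model"))
  saveRDS(object, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- readRDS(path)
  if (!inherits(obj, "attempt_model")) stopf("not an attempt_model file")
  if (!identical(obj$version, 1L)) stopf("unsupported model version")
  if (!identical(model_fingerprint(obj), obj$fingerprint)) {
    stopf("model fingerprint mismatch; file corrupted")
  }
  obj
}
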