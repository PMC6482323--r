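# Treatment-outcome article classification: a random forest (300 trees by
# default) over word-trigram counts of the preprocessed title + abstract.
# Label 1 = treatment success, 0 = treatment failure.

.check_labels <- function(x, labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("article_id", "label") %in% names(labels)))
    lab <- labels$label[match(x$article_id, labels$article_id)]
  } else if (!is.null(names(labels))) {
    lab <- labels[x$article_id]
  } else {
    stopifnot(length(labels) == nrow(x))
    lab <- labels
  }
  lab <- as.integer(lab)
  if (anyNA(lab)) stop("every article needs an outcome label", call. = FALSE)
  if (!all(lab %in% c(0L, 1L))) {
    stop("outcome labels must be 0 (failure) or 1 (success)", call. = FALSE)
  }
  lab
}

.classifier_tdm <- function(x, ngram, stopwords) {
  docs <- lapply(article_text(x), preprocess, stopwords = stopwords)
  build_tdm(docs, n = ngram, doc_ids = x$article_id)
}

# Fit a forest on a row subset of a prebuilt count matrix. Vocabulary
# pruning (document frequency >= min_df, capped at the max_features most
# document-frequent terms) is computed on the training rows only.
.fit_forest <- function(counts, vocab, rows, lab, n_trees, seed, min_df,
                        max_features, class_weights) {
  sub <- counts[rows, , drop = FALSE]
  df <- Matrix::colSums(sub > 0)
  keep <- which(df >= min_df)
  if (length(keep) == 0L) {
    stop("no trigram passes the document-frequency threshold; ",
         "lower `min_df`", call. = FALSE)
  }
  if (length(keep) > max_features) {
    keep <- keep[order(-df[keep], keep)][seq_len(max_features)]
    keep <- sort(keep)
  }
  xmat <- as.matrix(sub[, keep, drop = FALSE])
  colnames(xmat) <- paste0("f", seq_along(keep))
  y <- factor(lab, levels = c(0L, 1L))
  forest <- ranger::ranger(x = xmat, y = y, num.trees = n_trees,
                           probability = TRUE, seed = seed,
                           num.threads = 1L, min.node.size = 1L,
                           verbose = FALSE, class.weights = class_weights)
  list(forest = forest, keep = keep, vocabulary = vocab[keep])
}

.forest_scores <- function(fit, counts, rows) {
  xmat <- as.matrix(counts[rows, fit$keep, drop = FALSE])
  colnames(xmat) <- paste0("f", seq_along(fit$keep))
  pr <- stats::predict(fit$forest, data = xmat,
                       num.threads = 1L)$predictions
  as.numeric(pr[, "1"])
}

#' Train the treatment-outcome classifier
#'
#' Fits a random forest on the trigram term-document matrix of the
#' preprocessed article texts (title + abstract). The trigram vocabulary is
#' pruned to terms occurring in at least `min_df` training documents and
#' capped at the `max_features` most document-frequent terms (ties broken
#' by first occurrence), which keeps fits fast while retaining the
#' repeated, informative outcome phrases. Deterministic given `seed`.
#'
#' @param x A [corpus()].
#' @param labels Outcome labels (1 success, 0 failure): a data frame
#'   (`article_id`, `label`), a named vector, or a vector aligned with `x`.
#'   Both classes must be present.
#' @param n_trees Number of trees (default 300).
#' @param seed Integer seed.
#' @param min_df Minimum document frequency for a trigram (default 2).
#' @param max_features Vocabulary cap (default 2000).
#' @param ngram Gram size for features (default 3, per the pipeline design).
#' @param class_weights Optional named vector `c("0" = w0, "1" = w1)` for
#'   imbalanced corpora; `NULL` (default) weights classes equally.
#' @param stopwords Stopword list for [preprocess()].
#' @param features Optional precomputed [build_tdm()] object for `x` (built
#'   from preprocessed article texts with `doc_ids = x$article_id`); saves
#'   recomputation when training repeatedly on one corpus.
#' @return An object of class `outcome_classifier`.
#' @export
train_outcome_classifier <- function(x, labels, n_trees = 300L, seed = 1L,
                                     min_df = 2L, max_features = 2000L,
                                     ngram = 3L, class_weights = NULL,
                                     stopwords = default_stopwords(),
                                     features = NULL) {
  stopifnot(inherits(x, "corpus"), n_trees >= 1L)
  lab <- .check_labels(x, labels)
  if (length(unique(lab)) < 2L) {
    stop("training corpus must contain both outcome classes", call. = FALSE)
  }
  tdm <- features %||% .classifier_tdm(x, ngram, stopwords)
  stopifnot(identical(tdm$doc_ids, x$article_id))
  fit <- .fit_forest(tdm$counts, tdm$vocabulary, seq_len(nrow(x)), lab,
                     n_trees, seed, min_df, max_features, class_weights)
  structure(list(forest = fit$forest, vocabulary = fit$vocabulary,
                 keep = fit$keep, ngram = ngram, stopwords = stopwords,
                 n_trees = n_trees, seed = seed, min_df = min_df,
                 max_features = max_features, class_weights = class_weights,
                 n_train = nrow(x)),
            class = "outcome_classifier")
}

#' @export
print.outcome_classifier <- function(x, ...) {
  cat(sprintf(paste0("<outcome_classifier> random forest, %d trees, ",
                     "%d trigram features, trained on %d articles\n"),
              x$n_trees, length(x$vocabulary), x$n_train))
  invisible(x)
}

# counts of training-vocabulary n-grams for new documents
.doc_features <- function(model, docs) {
  m <- matrix(0, nrow = length(docs), ncol = length(model$vocabulary))
  for (d in seq_along(docs)) {
    grams <- .ngrams(docs[[d]], model$ngram)
    j <- match(grams, model$vocabulary)
    j <- j[!is.na(j)]
    if (length(j) > 0L) {
      tab <- table(j)
      m[d, as.integer(names(tab))] <- as.integer(tab)
    }
  }
  colnames(m) <- paste0("f", seq_along(model$vocabulary))
  m
}

#' Predict treatment outcome for articles
#'
#' Features are computed with the training vocabulary; unseen trigrams are
#' ignored. An article with no known trigram at all still gets a valid
#' label, with a warning that the prediction is low-information. An empty
#' abstract means the prediction comes from the title alone.
#'
#' @param object An `outcome_classifier`.
#' @param newdata A [corpus()] or data frame with `article_id`, `title`,
#'   `abstract`.
#' @param ... Unused.
#' @return Data frame with `article_id`, `label` (0/1) and `score` (the
#'   success-class probability).
#' @export
predict.outcome_classifier <- function(object, newdata, ...) {
  docs <- lapply(article_text(newdata), preprocess,
                 stopwords = object$stopwords)
  feats <- .doc_features(object, docs)
  empty <- rowSums(feats) == 0
  if (any(empty)) {
    warning(sum(empty), " article(s) share no trigram with the training ",
            "vocabulary; their predictions are low-information",
            call. = FALSE)
  }
  pr <- stats::predict(object$forest, data = feats,
                       num.threads = 1L)$predictions
  score <- pr[, "1"]
  data.frame(article_id = newdata$article_id,
             label = as.integer(score >= 0.5),
             score = as.numeric(score), stringsAsFactors = FALSE)
}

#' Precision, recall and F-score from confusion counts
#'
#' Positive-class metrics: precision tp/(tp+fp), recall tp/(tp+fn), F the
#' harmonic mean of the two. A zero denominator yields 0 for that metric
#' (and F is 0 whenever precision + recall is 0).
#'
#' @param tp,fp,fn,tn Non-negative integer confusion counts (positive class
#'   = treatment success, 1).
#' @return List with `precision`, `recall`, `f_score` and `confusion` (2x2
#'   matrix, rows = truth, columns = prediction).
#' @export
eval_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  confusion <- matrix(c(tn, fn, fp, tp), nrow = 2L,
                      dimnames = list(truth = c("0", "1"),
                                      predicted = c("0", "1")))
  list(precision = precision, recall = recall, f_score = f,
       confusion = confusion)
}

#' Evaluate the outcome classifier by stratified k-fold cross-validation
#'
#' Articles are assigned to `k_folds` stratified folds (per class, after a
#' seeded shuffle); each fold is predicted by a forest trained on the
#' others; the pooled out-of-fold predictions are scored once. The
#' term-document matrix is built once and folds subset its rows; vocabulary
#' pruning is recomputed inside each training fold. Metrics are reported
#' for the positive (success) class; the macro-averaged F is also returned.
#'
#' @inheritParams train_outcome_classifier
#' @param k_folds Number of folds (default 10); must be at least 2 and at
#'   most the size of the smaller class.
#' @return An object of class `outcome_eval`: `precision`, `recall`,
#'   `f_score`, `confusion`, `macro_f`, and the pooled `predictions`.
#' @export
evaluate_kfold <- function(x, labels, k_folds = 10L, n_trees = 300L,
                           seed = 1L, min_df = 2L, max_features = 2000L,
                           ngram = 3L, class_weights = NULL,
                           stopwords = default_stopwords(),
                           features = NULL) {
  stopifnot(inherits(x, "corpus"), k_folds >= 2L)
  lab <- .check_labels(x, labels)
  if (nrow(x) < k_folds) {
    stop("k_folds exceeds the number of articles", call. = FALSE)
  }
  if (length(unique(lab)) < 2L) {
    stop("corpus must contain both outcome classes", call. = FALSE)
  }
  if (min(table(lab)) < k_folds) {
    stop("a class would be absent from some training fold; ",
         "use a smaller k_folds", call. = FALSE)
  }
  tdm <- features %||% .classifier_tdm(x, ngram, stopwords)
  stopifnot(identical(tdm$doc_ids, x$article_id))
  set.seed(seed)
  fold <- integer(nrow(x))
  for (cl in unique(lab)) {
    idx <- sample(which(lab == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  pred <- integer(nrow(x)); score <- numeric(nrow(x))
  for (k in seq_len(k_folds)) {
    tr <- which(fold != k)
    fit <- .fit_forest(tdm$counts, tdm$vocabulary, tr, lab[tr], n_trees,
                       seed + k, min_df, max_features, class_weights)
    te <- which(fold == k)
    s <- .forest_scores(fit, tdm$counts, te)
    score[te] <- s
    pred[te] <- as.integer(s >= 0.5)
  }
  tp <- sum(lab == 1L & pred == 1L); fp <- sum(lab == 0L & pred == 1L)
  fn <- sum(lab == 1L & pred == 0L); tn <- sum(lab == 0L & pred == 0L)
  m <- eval_metrics(tp, fp, fn, tn)
  neg <- eval_metrics(tn, fn, fp, tp)   # metrics of the failure class
  structure(list(precision = m$precision, recall = m$recall,
                 f_score = m$f_score, confusion = m$confusion,
                 macro_f = (m$f_score + neg$f_score) / 2,
                 predictions = data.frame(article_id = x$article_id,
                                          truth = lab, label = pred,
                                          score = score, fold = fold,
                                          stringsAsFactors = FALSE),
                 k_folds = k_folds, n_trees = n_trees, seed = seed),
            class = "outcome_eval")
}

#' @export
print.outcome_eval <- function(x, ...) {
  cat(sprintf(paste0("<outcome_eval> %d-fold CV, %d trees\n",
                     "  precision %.4f  recall %.4f  F %.4f ",
                     "(positive class; macro-F %.4f)\n"),
              x$k_folds, x$n_trees, x$precision, x$recall, x$f_score,
              x$macro_f))
  print(x$confusion)
  invisible(x)
}
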