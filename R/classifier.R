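# Supervised n-gram sentiment classifier: a linear max-margin (SVM)
# multi-class model over n-gram term-frequency vectors, used as the
# automated counterpart to the rule engine. The margin optimization is
# delegated to e1071; feature extraction, vocabulary control and
# cross-validation live here.

ngram_features <- function(tokens, n_orders = 1:2) {
  out <- character()
  for (n in n_orders) {
    if (length(tokens) < n) next
    if (n == 1) out <- c(out, tokens)
    else {
      idx <- seq_len(length(tokens) - n + 1)
      grams <- vapply(idx, function(i)
        paste(tokens[i:(i + n - 1)], collapse = "_"), character(1))
      out <- c(out, grams)
    }
  }
  out
}

ngram_matrix <- function(token_lists, vocab, n_orders) {
  X <- matrix(0, nrow = length(token_lists), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(token_lists)) {
    tf <- table(ngram_features(token_lists[[i]], n_orders))
    hit <- intersect(names(tf), vocab)
    if (length(hit)) X[i, hit] <- as.numeric(tf[hit])
  }
  X
}

#' Train the n-gram sentiment classifier
#'
#' Builds n-gram term-frequency vectors (document-frequency pruned), then
#' fits a linear-kernel support vector machine (one-vs-one multi-class).
#' Training is deterministic for a given seed.
#'
#' @param token_lists list of token vectors (stemmed, normalized).
#' @param labels parallel character vector of class labels (>= 2 classes).
#' @param n_orders n-gram orders, default unigrams and bigrams.
#' @param min_df minimum document frequency for a feature.
#' @param max_features cap on vocabulary size (kept by document frequency).
#' @param cost SVM cost parameter.
#' @param seed RNG seed (shuffling / fold assignment downstream).
#' @return an object of class `ngram_classifier`.
#' @export
train_ngram_classifier <- function(token_lists, labels, n_orders = 1:2,
                                   min_df = 2, max_features = 2000,
                                   cost = 1, seed = 1) {
  if (length(token_lists) != length(labels))
    stop("token_lists and labels differ in length")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("need at least two classes to train a classifier")
  df <- table(unlist(lapply(token_lists, function(t)
    unique(ngram_features(t, n_orders)))))
  df <- df[df >= min_df]
  vocab <- names(sort(df, decreasing = TRUE))
  if (length(vocab) > max_features) vocab <- vocab[seq_len(max_features)]
  vocab <- sort(vocab)
  if (!length(vocab)) stop("empty vocabulary after pruning")
  X <- ngram_matrix(token_lists, vocab, n_orders)
  y <- factor(labels)
  set.seed(seed)
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  prior_class <- names(sort(table(labels), decreasing = TRUE))[1]
  structure(
    list(model = fit, vocab = vocab, n_orders = n_orders,
         levels = levels(y), prior_class = prior_class,
         config = list(min_df = min_df, max_features = max_features,
                       cost = cost, seed = seed)),
    class = "ngram_classifier"
  )
}

#' @export
print.ngram_classifier <- function(x, ...) {
  cat(sprintf(
    "<ngram_classifier: %d features (orders %s), classes: %s>\n",
    length(x$vocab), paste(x$n_orders, collapse = ","),
    paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predict sentiment labels with a trained n-gram classifier
#'
#' Tweets whose n-grams are entirely out of vocabulary fall back to the
#' training prior class and are flagged (attribute `oov`).
#'
#' @param object an `ngram_classifier`.
#' @param token_lists list of token vectors preprocessed like the training
#'   data.
#' @param ... unused.
#' @return character vector of labels with logical attribute `oov`.
#' @export
predict.ngram_classifier <- function(object, token_lists, ...) {
  if (is.null(object$model)) stop("classifier has not been trained")
  X <- ngram_matrix(token_lists, object$vocab, object$n_orders)
  oov <- rowSums(X) == 0
  out <- character(length(token_lists))
  if (any(!oov))
    out[!oov] <- as.character(stats::predict(object$model,
                                             X[!oov, , drop = FALSE]))
  out[oov] <- object$prior_class
  attr(out, "oov") <- oov
  out
}

#' k-fold cross-validation of the n-gram classifier
#'
#' @param token_lists list of token vectors.
#' @param labels parallel labels.
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @param ... passed to [train_ngram_classifier()].
#' @return list: per-fold macro F (`fold_f1`), mean macro F (`macro_f1`),
#'   pooled out-of-fold predictions (`predicted`).
#' @export
cv_ngram_classifier <- function(token_lists, labels, k = 5, seed = 1, ...) {
  n <- length(token_lists)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- character(n)
  f1 <- numeric(k)
  for (j in seq_len(k)) {
    tr <- fold != j
    m <- train_ngram_classifier(token_lists[tr], labels[tr], seed = seed, ...)
    pj <- predict(m, token_lists[!tr])
    pred[!tr] <- pj
    f1[j] <- macro_f1(pj, labels[!tr])
  }
  list(fold_f1 = f1, macro_f1 = mean(f1), predicted = pred)
}
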