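#' K-nearest-neighbour classification by cosine similarity
#'
#' Exact exhaustive search: each query is compared against every reference
#' embedding by cosine similarity, and the majority label among the `k` most
#' similar references is returned. Ties are broken in favour of the tied
#' class containing the single nearest neighbour.
#'
#' @param reference_embeddings numeric matrix (references by dims).
#' @param reference_labels vector of labels, one per reference row.
#' @param query_embeddings numeric matrix (queries by dims).
#' @param k neighbours to vote (default 5).
#' @return character vector of predicted labels, one per query.
#' @export
knn_classify <- function(reference_embeddings, reference_labels,
                         query_embeddings, k = 5L) {
  stopifnot(is.matrix(reference_embeddings), is.matrix(query_embeddings),
            ncol(reference_embeddings) == ncol(query_embeddings),
            length(reference_labels) == nrow(reference_embeddings))
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(reference_embeddings)) {
    stop("k (", k, ") exceeds the number of references (",
         nrow(reference_embeddings), ")")
  }
  labels <- as.character(reference_labels)
  # cosine similarity matrix via row-normalized cross product
  rn <- reference_embeddings / sqrt(rowSums(reference_embeddings^2))
  qn <- query_embeddings / sqrt(rowSums(query_embeddings^2))
  sim <- qn %*% t(rn)  # queries x references
  preds <- character(nrow(sim))
  for (i in seq_len(nrow(sim))) {
    ord <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    votes <- table(labels[ord])
    top <- names(votes)[votes == max(votes)]
    preds[i] <- if (length(top) == 1L) top else {
      labels[ord][labels[ord] %in% top][1]  # nearest neighbour among tied
    }
  }
  preds
}

#' Multilayer-perceptron classification with repeated random splits
#'
#' Fits a single-hidden-layer perceptron (via \pkg{nnet}) on a random
#' train/test split of the features, repeated `repeats` times, and reports
#' per-repeat test accuracy. Defaults mirror the EC-superclass experiment:
#' 512 hidden nodes, 20 epochs, an 80/20 split, 10 repeats. `epochs` maps to
#' \code{nnet}'s `maxit` (nnet is a full-batch quasi-Newton optimizer, not a
#' minibatch one).
#'
#' @param features numeric matrix (samples by dims).
#' @param labels vector of class labels.
#' @param hidden_nodes hidden-layer width (default 512).
#' @param epochs optimizer iterations (default 20).
#' @param split_fraction training fraction of each random split (default 0.8).
#' @param repeats number of random splits (default 10).
#' @param seed RNG seed; repeat r uses `seed + r - 1`.
#' @return list with `accuracy` (per-repeat vector), `mean`, `sd`, and
#'   `models` (the fitted nnet objects).
#' @export
train_mlp <- function(features, labels, hidden_nodes = 512L, epochs = 20L,
                      split_fraction = 0.8, repeats = 10L, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two classes")
  acc <- numeric(repeats)
  models <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    n <- nrow(features)
    tr <- sample.int(n, round(split_fraction * n))
    te <- setdiff(seq_len(n), tr)
    y <- nnet::class.ind(labels[tr])
    fit <- nnet::nnet(features[tr, , drop = FALSE], y, size = hidden_nodes,
                      maxit = epochs, softmax = TRUE, trace = FALSE,
                      MaxNWts = 1e7)
    pr <- stats::predict(fit, features[te, , drop = FALSE])
    pred <- colnames(pr)[max.col(pr, ties.method = "first")]
    acc[r] <- mean(pred == as.character(labels[te]))
    models[[r]] <- fit
  }
  list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc), models = models)
}

#' Confusion matrix from predicted and true labels
#'
#' @param truth,predicted label vectors of equal length.
#' @return square integer matrix (rows = truth, columns = predicted) over the
#'   union of observed classes.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(c(as.character(truth), as.character(predicted))))
  table(factor(as.character(truth), levels = classes),
        factor(as.character(predicted), levels = classes))
}

#' Classification metrics: accuracy, MCC and CEN
#'
#' Accuracy is trace/total. MCC is the multiclass Matthews correlation
#' coefficient in its covariance form. CEN is the confusion-entropy measure:
#' per-class misclassification entropies (log base `2(K-1)` for `K` classes)
#' weighted by the class's share of classifications and summed; it is 0 for a
#' perfect diagonal matrix and grows with off-diagonal confusion.
#'
#' @param cm a square confusion matrix (rows = truth, columns = predicted).
#' @return named list with `accuracy`, `mcc`, `cen`.
#' @export
#' @examples
#' cm <- matrix(c(8, 1, 2, 9), 2, 2)
#' classification_metrics(cm)
classification_metrics <- function(cm) {
  cm <- as.matrix(unclass(cm))
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  accuracy <- sum(diag(cm)) / total

  # Matthews correlation, covariance form (truth t_k = row sums,
  # predictions p_k = column sums, c = trace, s = total)
  tk <- rowSums(cm); pk <- colSums(cm); cc <- sum(diag(cm)); s <- total
  denom <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  mcc <- if (denom == 0) 0 else (cc * s - sum(tk * pk)) / denom

  # confusion entropy
  cen <- 0
  if (K >= 2) {
    logb <- function(x) log(x, base = 2 * (K - 1))
    for (j in seq_len(K)) {
      denom_j <- sum(cm[j, ]) + sum(cm[, j])
      if (denom_j == 0) next
      w_j <- denom_j / (2 * s)
      cen_j <- 0
      for (k in seq_len(K)) {
        if (k == j) next
        pjk <- cm[j, k] / denom_j
        pkj <- cm[k, j] / denom_j
        if (pjk > 0) cen_j <- cen_j - pjk * logb(pjk)
        if (pkj > 0) cen_j <- cen_j - pkj * logb(pkj)
      }
      cen <- cen + w_j * cen_j
    }
  }
  list(accuracy = accuracy, mcc = mcc, cen = cen)
}
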