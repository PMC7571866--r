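#' Stratified k-fold cross-validation of the RUSBoost ensemble
#'
#' Partitions the observations into k disjoint folds, stratified by class
#' so the 12-observation minority class is spread as evenly as the
#' arithmetic allows (per-class fold sizes differ by at most one). Each
#' fold is scored by an ensemble fitted on the other k-1 folds; all
#' out-of-fold predictions are pooled into a single confusion matrix,
#' accuracy, PPV, TPR/FPR and ROC/AUC. Pooling (rather than per-fold
#' averaging) keeps the metrics well-defined when a fold holds only 2-3
#' minority observations.
#'
#' @param features data.frame of numeric predictors
#' @param labels class labels (two classes, each with at least k members)
#' @param k number of folds
#' @param seed integer seed controlling the fold assignment and each
#'   fold's ensemble fit
#' @param positive positive class name
#' @param ... passed to [rusboost_fit()] (n_rounds, learning_rate, ...)
#' @return an object of class `cv_result`: `fold_assignments`,
#'   `confusion_matrix` (rows = truth, cols = predicted), `accuracy`,
#'   `ppv`, `tpr_acs`, `fpr`, `roc_points`, `auc`, `scores`, `predicted`
#' @export
stratified_cv <- function(features, labels, k = 5, seed = NULL,
                          positive = "acs", ...) {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(nrow(features) == n)
  counts <- table(labels)
  if (any(counts < k)) {
    small <- names(counts)[counts < k]
    stop(sprintf(
      paste("class '%s' has only %d observations, fewer than k = %d folds;",
            "reduce k or collect more observations of that class"),
      small[1], counts[small[1]], k), call. = FALSE)
  }

  with_local_seed(seed, {
    fold <- integer(n)
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fit_seeds <- sample.int(2^30, k)

    scores <- numeric(n)
    predicted <- character(n)
    for (f in seq_len(k)) {
      train <- fold != f
      ens <- rusboost_fit(features[train, , drop = FALSE], labels[train],
                          positive = positive, seed = fit_seeds[f], ...)
      scores[!train] <- predict_scores(ens, features[!train, , drop = FALSE])
      predicted[!train] <- predict_labels(ens, features[!train, , drop = FALSE])
    }

    classes <- c(setdiff(sort(unique(labels)), positive), positive)
    cm <- table(truth = factor(labels, levels = classes),
                predicted = factor(predicted, levels = classes))
    tp <- cm[positive, positive]
    fn <- sum(cm[positive, ]) - tp
    fp <- sum(cm[, positive]) - tp
    tn <- sum(cm) - tp - fn - fp
    roc <- roc_auc(scores, labels, positive = positive)
    structure(
      list(fold_assignments = fold, confusion_matrix = cm,
           accuracy = (tp + tn) / n,
           ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           tpr_acs = tp / (tp + fn), fpr = fp / (fp + tn),
           roc_points = roc$roc_points, auc = roc$auc,
           scores = scores, predicted = predicted, k = k, seed = seed),
      class = "cv_result"
    )
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV (pooled out-of-fold metrics)\n", x$k))
  print(x$confusion_matrix)
  cat(sprintf("accuracy %.3f | PPV %.3f | TPR %.3f | FPR %.3f | AUC %.3f\n",
              x$accuracy, x$ppv, x$tpr_acs, x$fpr, x$auc))
  invisible(x)
}

#' Plot the pooled out-of-fold ROC curve
#'
#' @param cv a [stratified_cv()] result
#' @export
plot_roc <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  graphics::plot(cv$roc_points$fpr, cv$roc_points$tpr, type = "s",
                 lwd = 2, col = "firebrick", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Pooled out-of-fold ROC (AUC = %.3f)", cv$auc))
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(NULL)
}
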