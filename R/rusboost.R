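# RUSBoost: random undersampling + AdaBoost-style reweighting with
# depth-limited rpart weak learners. Each round trains on a class-balanced
# subsample (all minority observations plus a weight-respecting random draw
# of equally many majority observations) but evaluates its weighted error
# on the full training set, so boosting compensates for the information the
# undersampling discards. The two-class AdaBoost update is used; for binary
# labels it is equivalent to the multi-class pseudo-loss formulation.

#' Fit a RUSBoosted tree ensemble
#'
#' @param features data.frame (or matrix) of numeric predictors
#' @param labels vector of class labels; exactly two classes must be
#'   present. The minority class is undersampling's protected class.
#' @param n_rounds maximum number of boosting rounds
#' @param learning_rate shrinkage applied to the learner weights, in (0, 1]
#' @param max_splits maximum number of splits per tree (trees are grown
#'   with `cp = 0` then pruned back to at most this many splits)
#' @param positive name of the positive class scored by
#'   [predict_scores()]; defaults to the minority class
#' @param seed integer; the same seed yields an identical ensemble
#' @param max_retries rounds whose weighted error reaches 0.5 are resampled
#'   up to this many times before boosting stops
#' @return an object of class `rusboost`: weak learners, learner weights
#'   `alpha`, class names, and fitting metadata. The attribute
#'   `weight_sums` records the boosting-weight total after each round's
#'   renormalization.
#' @export
rusboost_fit <- function(features, labels, n_rounds = 30,
                         learning_rate = 0.1, max_splits = 20,
                         positive = NULL, seed = NULL, max_retries = 10) {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop(sprintf("need exactly 2 classes to fit, got %d (%s)",
                 length(classes), paste(classes, collapse = ", ")),
         call. = FALSE)
  }
  check_that(n_rounds >= 1, "n_rounds", "must be >= 1")
  check_that(learning_rate > 0 && learning_rate <= 1, "learning_rate",
             "must be in (0, 1]")
  counts <- table(labels)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(classes, minority)
  if (is.null(positive)) positive <- minority
  n <- nrow(features)
  d <- cbind(.label = factor(labels, levels = classes), features)

  with_local_seed(seed, {
    w <- rep(1 / n, n)
    learners <- list()
    alphas <- numeric()
    weight_sums <- numeric()
    round_log <- list()
    min_idx <- which(labels == minority)
    maj_idx <- which(labels == majority)

    for (t in seq_len(n_rounds)) {
      fitted <- NULL
      for (r in seq_len(max_retries)) {
        sub_maj <- sample(maj_idx, size = length(min_idx),
                          prob = w[maj_idx])
        idx <- c(min_idx, sub_maj)
        tree <- fit_weak_tree(d[idx, , drop = FALSE], w[idx], max_splits)
        pred <- predict_tree(tree, features)
        eps <- sum(w[pred != labels])
        if (eps < 0.5) {
          fitted <- list(tree = tree, eps = eps, n_maj = length(sub_maj))
          break
        }
      }
      if (is.null(fitted)) break  # no usable learner this round
      eps <- max(fitted$eps, 1e-10)
      alphas <- c(alphas, learning_rate * log((1 - eps) / eps))
      learners <- c(learners, list(fitted$tree))
      round_log[[length(round_log) + 1]] <- data.frame(
        round = t, eps = fitted$eps, n_minority = length(min_idx),
        n_majority_sampled = fitted$n_maj)
      if (fitted$eps == 0) { weight_sums <- c(weight_sums, sum(w)); break }
      beta <- eps / (1 - eps)
      correct <- predict_tree(fitted$tree, features) == labels
      w[correct] <- w[correct] * beta
      w <- w / sum(w)
      weight_sums <- c(weight_sums, sum(w))
    }

    if (length(learners) == 0) {
      stop("no usable boosting rounds: every subsample gave weighted error >= 0.5",
           call. = FALSE)
    }
    structure(
      list(weak_learners = learners, alpha = alphas, classes = classes,
           positive = positive, minority = minority,
           n_rounds = n_rounds, learning_rate = learning_rate,
           max_splits = max_splits, feature_names = names(features),
           round_log = do.call(rbind, round_log)),
      class = "rusboost", weight_sums = weight_sums
    )
  })
}

# Grow an rpart tree with cp = 0, then prune back to at most `max_splits`
# splits using the complexity table.
fit_weak_tree <- function(d, w, max_splits) {
  fm <- stats::as.formula(".label ~ .")
  environment(fm) <- environment()
  tree <- rpart::rpart(fm, data = d, weights = w, method = "class",
                       control = rpart::rpart.control(
                         cp = 0, minsplit = 2, minbucket = 1,
                         maxdepth = 30, xval = 0, maxsurrogate = 0,
                         maxcompete = 0))
  cpt <- tree$cptable
  ok <- which(cpt[, "nsplit"] <= max_splits)
  target <- ok[which.max(cpt[ok, "nsplit"])]
  if (cpt[target, "nsplit"] < max(cpt[, "nsplit"])) {
    tree <- rpart::prune(tree, cp = cpt[target, "CP"] + 1e-12)
  }
  tree
}

predict_tree <- function(tree, features) {
  as.character(stats::predict(tree, newdata = as.data.frame(features),
                              type = "class"))
}

#' @export
print.rusboost <- function(x, ...) {
  cat(sprintf(
    "RUSBoost ensemble: %d weak learners (max %d rounds), positive class '%s'\n",
    length(x$weak_learners), x$n_rounds, x$positive))
  invisible(x)
}

#' Ensemble scores for the positive class
#'
#' The normalized weighted vote: `sum(alpha_t * [tree_t votes positive]) /
#' sum(alpha_t)`, in \[0, 1\].
#'
#' @param ensemble a fitted [rusboost_fit()] ensemble
#' @param features data.frame of predictors
#' @return numeric vector of positive-class scores
#' @export
predict_scores <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "rusboost"))
  if (length(ensemble$weak_learners) == 0) {
    stop("ensemble has no fitted learners", call. = FALSE)
  }
  features <- as.data.frame(features)
  votes <- vapply(ensemble$weak_learners, function(tr) {
    as.numeric(predict_tree(tr, features) == ensemble$positive)
  }, numeric(nrow(features)))
  votes <- matrix(votes, nrow = nrow(features))
  as.numeric(votes %*% ensemble$alpha) / sum(ensemble$alpha)
}

#' Hard class labels from ensemble scores
#'
#' The positive (costlier-to-miss) class is predicted when the score
#' reaches 0.5, ties included.
#'
#' @inheritParams predict_scores
#' @return character vector of predicted labels
#' @export
predict_labels <- function(ensemble, features) {
  s <- predict_scores(ensemble, features)
  ifelse(s >= 0.5, ensemble$positive,
         setdiff(ensemble$classes, ensemble$positive))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (tied scores enter
#' simultaneously) and accumulates (FPR, TPR) points; the AUC is the
#' trapezoid-rule area, which equals the Mann-Whitney probability that a
#' random positive outscores a random negative, with half credit for ties.
#'
#' @param scores numeric scores, larger = more positive
#' @param labels class labels
#' @param positive name of the positive class
#' @return list with `roc_points` (data.frame of fpr, tpr, one row per
#'   threshold plus the endpoints) and `auc`
#' @export
roc_auc <- function(scores, labels, positive = "acs") {
  labels <- as.character(labels)
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC is undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- is_pos[ord]
  # cumulative counts at each distinct-score boundary
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc_points = roc, auc = auc)
}
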