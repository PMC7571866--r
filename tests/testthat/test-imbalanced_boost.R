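test_that("RUSBoost separates a linearly separable imbalanced toy set", {
  toy <- toy_separable()
  # brute-force check that an axis-aligned threshold separates the classes
  expect_true(max(toy$features$x[toy$labels == "healthy"]) <
                min(toy$features$x[toy$labels == "acs"]))
  ens <- rusboost_fit(toy$features, toy$labels, seed = 1)
  expect_identical(predict_labels(ens, toy$features), toy$labels)
  expect_true(all(ens$alpha >= 0))
  expect_lte(length(ens$weak_learners), ens$n_rounds)
})

test_that("every round trains on a 1:1 undersampled class balance", {
  toy <- toy_separable(30, 6)
  set.seed(10)
  noisy <- toy$features + matrix(rnorm(72, 0, 1.5), 36, 2)
  ens <- rusboost_fit(noisy, toy$labels, n_rounds = 15, seed = 2)
  expect_true(all(ens$round_log$n_majority_sampled == ens$round_log$n_minority))
  expect_true(all(ens$round_log$eps < 0.5))
})

test_that("boosting weights stay a normalized distribution every round", {
  toy <- toy_separable(30, 6)
  set.seed(11)
  noisy <- toy$features + matrix(rnorm(72, 0, 2), 36, 2)
  ens <- rusboost_fit(noisy, toy$labels, n_rounds = 20, seed = 3)
  expect_true(all(abs(attr(ens, "weight_sums") - 1) < 1e-9))
})

test_that("fitting is deterministic given a seed and rejects degenerate labels", {
  toy <- toy_separable(25, 5)
  set.seed(12)
  noisy <- toy$features + matrix(rnorm(60, 0, 1), 30, 2)
  a <- rusboost_fit(noisy, toy$labels, seed = 99)
  b <- rusboost_fit(noisy, toy$labels, seed = 99)
  expect_identical(predict_scores(a, noisy), predict_scores(b, noisy))
  expect_identical(a$alpha, b$alpha)
  expect_error(rusboost_fit(noisy, rep("healthy", 30)), "2 classes")
})

test_that("scores are the normalized weighted vote for the positive class", {
  # tree voting acs for x > 0, tree voting healthy always
  d_split <- data.frame(x = c(-2, -1, 1, 2))
  tree_pos <- rpart::rpart(y ~ x,
                           data = cbind(y = factor(c("healthy", "healthy", "acs", "acs"),
                                                   levels = c("acs", "healthy")),
                                        d_split),
                           method = "class",
                           control = rpart::rpart.control(cp = 0, minsplit = 2))
  tree_neg <- rpart::rpart(y ~ x,
                           data = cbind(y = factor(rep("healthy", 4),
                                                   levels = c("acs", "healthy")),
                                        d_split),
                           method = "class", control = rpart::rpart.control(cp = 0))
  ens <- structure(list(weak_learners = list(tree_pos, tree_neg),
                        alpha = c(3, 1), classes = c("acs", "healthy"),
                        positive = "acs"), class = "rusboost")
  # point with x > 0: votes (acs, healthy) with weights (3, 1) -> 0.75
  expect_equal(predict_scores(ens, data.frame(x = 5)), 0.75)
  expect_equal(predict_scores(ens, data.frame(x = -5)), 0)
  ens$alpha <- c(1, 1)
  # tie at 0.5 resolves to the costlier-to-miss positive class
  expect_identical(predict_labels(ens, data.frame(x = 5)), "acs")
  empty <- structure(list(weak_learners = list(), alpha = numeric()),
                     class = "rusboost")
  expect_error(predict_scores(empty, data.frame(x = 1)), "no fitted learners")
})

test_that("ROC sweep handles the canonical small cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("acs", "acs", "healthy", "healthy"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("acs", "healthy"), 5))$auc, 0.5)
  # 4 (acs, healthy) pairs: 3 wins, 1 loss -> 0.75
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6),
                       c("acs", "healthy", "acs", "healthy"))$auc, 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c("acs", "acs")), "both classes")
})

test_that("sweep AUC equals brute-force Mann-Whitney on random instances", {
  set.seed(20)
  for (trial in 1:200) {
    n <- sample(4:50, 1)
    labels <- c("acs", "healthy",
                sample(c("acs", "healthy"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("sweep AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (trial in 1:20) {
    labels <- sample(c("acs", "healthy"), 40, replace = TRUE,
                     prob = c(0.25, 0.75))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(40), 2)
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(labels, scores, levels = c("healthy", "acs"),
                          direction = "<"))))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})
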