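test_that("fold plans partition the data with the documented 85:15 split", {
  plan <- make_fold_plan(120, fold_size = 10, seed = 3)
  expect_equal(length(plan$folds), 12L)
  for (fold in plan$folds) {
    expect_equal(length(fold$test), 10L)
    expect_equal(length(fold$val), 17L)    # round-half-up(0.15 * 110)
    expect_equal(length(fold$train), 93L)
    expect_equal(sort(c(fold$test, fold$val, fold$train)), 1:120)
    expect_equal(length(intersect(fold$test, fold$train)), 0L)
    expect_equal(length(intersect(fold$test, fold$val)), 0L)
    expect_equal(length(intersect(fold$val, fold$train)), 0L)
  }
  # every sample tested exactly once across folds
  tested <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_equal(sort(tested), 1:120)

  plan60 <- make_fold_plan(60, fold_size = 10, seed = 4)
  expect_equal(length(plan60$folds), 6L)
  expect_equal(length(plan60$folds[[1]]$val), 8L)   # round-half-up(7.5)
  expect_equal(length(plan60$folds[[1]]$train), 42L)
})

test_that("a non-divisible sample count yields a smaller final fold", {
  plan <- make_fold_plan(23, fold_size = 10, seed = 5)
  sizes <- vapply(plan$folds, function(f) length(f$test), integer(1))
  expect_equal(sizes, c(10L, 10L, 3L))
  expect_equal(sort(unlist(lapply(plan$folds, `[[`, "test"))), 1:23)
  expect_error(make_fold_plan(10, fold_size = 10), "must be smaller")
})

test_that("fold plans are reproducible for a fixed seed", {
  p1 <- make_fold_plan(60, seed = 7)
  p2 <- make_fold_plan(60, seed = 7)
  expect_identical(p1$order, p2$order)
  expect_identical(p1$folds, p2$folds)
})

test_that("AUROC handles separation, ties and midranks", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0)
  expect_error(auroc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUROC equals the pair-counting oracle on random instances", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:2, 1))  # coarse rounding forces ties
    expect_equal(auroc(scores, labels), auroc_pair_count(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  for (i in 1:20) {
    n <- 30
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("sensitivity/specificity use the >= threshold convention", {
  perfect <- sensitivity_specificity(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity, 1.0)
  expect_equal(perfect$specificity, 1.0)
  # boundary score counts as a positive prediction
  ss <- sensitivity_specificity(c(0.5, 0.4), c(1, 0), threshold = 0.5)
  expect_equal(ss$sensitivity, 1.0)
  expect_equal(ss$specificity, 1.0)
  ss2 <- sensitivity_specificity(c(0.7, 0.4, 0.3), c(1, 1, 0))
  expect_equal(ss2$sensitivity, 0.5)
  expect_error(sensitivity_specificity(c(0.7, 0.4), c(1, 1)), "both classes")
})

test_that("the experiment scores every sample once and aggregates trials", {
  inv <- tiny_inventory(4)
  dataset <- quick_labelled_set(inv, n_per_class = 12, len = 12, seed = 61)
  res <- run_experiment(dataset, inv,
                        config = engine_config("gru", TRUE, 4),
                        train_config = engine_train_config(max_epochs = 4,
                                                           patience = 3),
                        n_trials = 2, fold_size = 8, base_seed = 3)
  expect_equal(nrow(res$per_trial), 2L)
  expect_true(all(res$per_trial$auroc >= 0 & res$per_trial$auroc <= 1))
  for (p in res$pooled) {
    expect_equal(length(p$scores), 24L)
    expect_false(anyNA(p$scores))
  }
  expect_equal(res$summary$metric, c("auroc", "sensitivity", "specificity"))
  expect_equal(res$summary$mean[1], mean(res$per_trial$auroc))
  expect_error(run_experiment(dataset[1:12], inv), "both classes")
})
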