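#' Cross-validation fold plan
#'
#' Implements the evaluation protocol's data handling: samples are shuffled
#' once (so the two classes mix), then test folds of `fold_size` samples
#' are taken sequentially through the shuffled order until every sample has
#' been tested (the last fold may be smaller when `n_samples` is not
#' divisible). For each fold the remaining samples are split into training
#' and validation sets with an 85:15 ratio; the validation count is
#' `round-half-up(val_ratio * remaining)`.
#'
#' @param n_samples total number of samples (> `fold_size`).
#' @param fold_size test-fold size (default 10).
#' @param val_ratio validation fraction of the non-test samples
#'   (default 0.15).
#' @param seed RNG seed for the shuffle.
#' @return an object of class `fold_plan`: list with `order` (shuffled
#'   sample indices) and `folds`, each fold a list of disjoint index sets
#'   `test`, `val`, `train` covering all of `1:n_samples`.
#' @export
make_fold_plan <- function(n_samples, fold_size = 10, val_ratio = 0.15,
                           seed = 1) {
  if (fold_size >= n_samples) {
    stop("fold_size (", fold_size, ") must be smaller than n_samples (",
         n_samples, ")")
  }
  set.seed(seed)
  order <- sample.int(n_samples)
  starts <- seq(1, n_samples, by = fold_size)
  folds <- lapply(starts, function(s) {
    test <- order[s:min(s + fold_size - 1, n_samples)]
    rest <- setdiff(order, test)
    n_val <- floor(val_ratio * length(rest) + 0.5)  # round half up
    val <- rest[seq_len(n_val)]
    train <- setdiff(rest, val)
    list(test = test, val = val, train = train)
  })
  structure(list(order = order, folds = folds, n_samples = n_samples,
                 fold_size = fold_size, val_ratio = val_ratio, seed = seed),
            class = "fold_plan")
}

#' Area under the ROC curve
#'
#' Probability that a uniformly random positive sample receives a higher
#' score than a uniformly random negative one, with ties counted as one
#' half (midrank / Mann-Whitney formulation).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = AD); both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity and specificity at a threshold
#'
#' Predicts AD when `score >= threshold` (boundary counts as positive).
#'
#' @inheritParams auroc
#' @param threshold decision threshold (default 0.5).
#' @return list with `sensitivity` = TP/(TP+FN) and `specificity` =
#'   TN/(TN+FP).
#' @export
sensitivity_specificity <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (length(unique(labels)) < 2) {
    stop("sensitivity/specificity require both classes to be present")
  }
  pred <- as.integer(scores >= threshold)
  list(
    sensitivity = sum(pred == 1 & labels == 1) / sum(labels == 1),
    specificity = sum(pred == 0 & labels == 0) / sum(labels == 0)
  )
}

#' Run the repeated cross-validation experiment
#'
#' One trial = a fresh shuffled fold plan; for every fold an engine is
#' trained from scratch on that fold's training set (validation set drives
#' early stopping) and scores the fold's test samples. Test scores pooled
#' across all folds of the trial give one AUROC plus sensitivity and
#' specificity. Trials differ only in their seed; results are reported
#' per-trial and as mean and standard deviation across trials.
#'
#' @param dataset list of labelled [feature_sequence()] objects.
#' @param inventory the [token_inventory()].
#' @param config an [engine_config()].
#' @param train_config an [engine_train_config()]; its seed is re-derived
#'   per trial from `base_seed`.
#' @param n_trials number of trials (default 6).
#' @param fold_size,val_ratio see [make_fold_plan()].
#' @param threshold decision threshold for sensitivity/specificity.
#' @param base_seed integer; trial t uses seed `base_seed + t - 1`.
#' @return an `experiment_result`: list with `per_trial` (data frame:
#'   trial, auroc, sensitivity, specificity), `summary` (mean and sd per
#'   metric) and `pooled` (per-trial pooled scores and labels).
#' @export
run_experiment <- function(dataset, inventory, config = engine_config(),
                           train_config = engine_train_config(),
                           n_trials = 6, fold_size = 10, val_ratio = 0.15,
                           threshold = 0.5, base_seed = 1) {
  labels_all <- vapply(dataset, seq_label, integer(1))
  if (length(unique(labels_all)) < 2) {
    stop("dataset must contain both classes")
  }
  n <- length(dataset)
  trials <- vector("list", n_trials)
  pooled <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    trial_seed <- as.integer(base_seed + t - 1)
    plan <- make_fold_plan(n, fold_size = fold_size, val_ratio = val_ratio,
                           seed = trial_seed)
    scores <- rep(NA_real_, n)
    for (f in seq_along(plan$folds)) {
      fold <- plan$folds[[f]]
      tc <- train_config
      tc$seed <- trial_seed * 1000L + f
      fit <- train_engine(dataset[fold$train], dataset[fold$val], inventory,
                          config = config, train_config = tc)
      for (i in fold$test) {
        scores[i] <- score_sequence(fit$model, dataset[[i]])
      }
    }
    stopifnot(!anyNA(scores))  # every sample tested exactly once
    ss <- sensitivity_specificity(scores, labels_all, threshold)
    trials[[t]] <- data.frame(trial = t,
                              auroc = auroc(scores, labels_all),
                              sensitivity = ss$sensitivity,
                              specificity = ss$specificity)
    pooled[[t]] <- list(scores = scores, labels = labels_all)
  }
  per_trial <- do.call(rbind, trials)
  summarise <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  structure(list(
    per_trial = per_trial,
    summary = data.frame(
      metric = c("auroc", "sensitivity", "specificity"),
      mean = c(mean(per_trial$auroc), mean(per_trial$sensitivity),
               mean(per_trial$specificity)),
      sd = c(summarise(per_trial$auroc)["sd"],
             summarise(per_trial$sensitivity)["sd"],
             summarise(per_trial$specificity)["sd"])
    ),
    pooled = pooled
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", nrow(x$per_trial), " trial(s)\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-12s %.3f +/- %.2f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}
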