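#' Repeated shuffle-split evaluation of one method
#'
#' The labeled matrix is randomly partitioned `n_iterations` times into a
#' stratified train/test split (`1 - test_fraction` / `test_fraction`). Per
#' iteration the configured model is fitted on the training part and scored
#' on the test part (ROC AUC from the model's continuous decision score, F1
#' and plain accuracy from the hard labels), and a stratified k-fold
#' cross-validation accuracy is computed within the training part. The four
#' metrics are averaged over iterations. The positive class for F1 and the
#' ROC score is the second label level.
#'
#' @param pangenome a labeled `pangenome` with at least 10 genomes per group.
#' @param config a [selector_config()]; its `method` and model
#'   hyperparameters are used, its `seed` drives all splits.
#' @param n_iterations number of shuffled partitions (default 100).
#' @param test_fraction held-out fraction per partition (default 0.1).
#' @param cv_folds folds for the within-training cross-validation accuracy
#'   (default 10).
#' @return A `metrics_summary`: per-method means of ROC AUC, F1, CV accuracy
#'   and accuracy plus the per-iteration table.
#' @export
evaluate_method <- function(pangenome, config, n_iterations = 100L,
                            test_fraction = 0.1, cv_folds = 10L) {
  assert_labeled(pangenome)
  stopifnot(inherits(config, "selector_config"))
  n_iterations <- check_count(n_iterations, "n_iterations", min = 1L)
  cv_folds <- check_count(cv_folds, "cv_folds", min = 2L)
  check_fraction(test_fraction, "test_fraction", allow_zero = FALSE,
                 allow_one = FALSE)
  labels <- pangenome$labels
  if (min(table(labels)) < 10L) {
    stop("evaluation needs at least 10 genomes per group", call. = FALSE)
  }
  X <- pangenome$presence
  storage.mode(X) <- "double"
  rows <- lapply(seq_len(n_iterations), function(it) {
    s <- derive_seed(config$seed, 100000L + it)
    test_idx <- withr::with_seed(s, stratified_test_idx(labels, test_fraction))
    if (length(unique(labels[test_idx])) < 2L) {
      test_idx <- withr::with_seed(derive_seed(config$seed, 200000L + it),
                                   stratified_test_idx(labels, test_fraction))
      if (length(unique(labels[test_idx])) < 2L) {
        stop(sprintf("iteration %d: test split contains a single class", it),
             call. = FALSE)
      }
    }
    train_idx <- setdiff(seq_along(labels), test_idx)
    m <- fit_and_score(X, labels, train_idx, test_idx, config, s)
    cv <- cv_accuracy(X[train_idx, , drop = FALSE],
                      droplevels(labels[train_idx]),
                      config, cv_folds, derive_seed(s, 17L), warm = m$fit)
    data.frame(iteration = it, roc_auc = m$auc, f1 = m$f1,
               cv_accuracy = cv, accuracy = m$accuracy)
  })
  tab <- do.call(rbind, rows)
  structure(list(method = config$method,
                 mean_roc_auc = mean(tab$roc_auc),
                 mean_f1 = mean(tab$f1),
                 mean_cv_accuracy = mean(tab$cv_accuracy),
                 mean_accuracy = mean(tab$accuracy),
                 n_iterations = n_iterations,
                 per_iteration_table = tab),
            class = "metrics_summary")
}

# Stratified test indices: at least one genome per group in the test set.
stratified_test_idx <- function(labels, test_fraction) {
  unlist(lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    sample(idx, max(1L, round(test_fraction * length(idx))))
  }), use.names = FALSE)
}

# Fit the configured model on train_idx, return test metrics and the fit.
fit_and_score <- function(X, labels, train_idx, test_idx, config, seed) {
  positive <- levels(labels)[2L]
  ytr <- droplevels(labels[train_idx])
  yte <- labels[test_idx]
  Xtr <- X[train_idx, , drop = FALSE]
  Xte <- X[test_idx, , drop = FALSE]
  sc <- model_scores(Xtr, ytr, Xte, config, seed)
  pred <- factor(ifelse(sc$score > sc$cut, positive, levels(labels)[1L]),
                 levels = levels(labels))
  auc <- as.numeric(pROC::auc(response = yte, predictor = sc$score,
                              levels = levels(labels), direction = "<",
                              quiet = TRUE))
  list(auc = auc, f1 = f1_score(yte, pred, positive),
       accuracy = mean(pred == yte), fit = sc$fit)
}

# Continuous decision scores for the test matrix; `cut` is the hard-label
# decision boundary on the score scale.
model_scores <- function(Xtr, ytr, Xte, config, seed, warm = NULL) {
  if (config$method == "lr") {
    y01 <- as.numeric(ytr == levels(ytr)[2L])
    fit <- fit_lr_ridge(Xtr, y01, max_iter = config$lr_max_iterations,
                        start = warm$par)
    list(score = predict_lr_score(fit, Xte), cut = 0.5, fit = fit)
  } else if (config$method == "svm") {
    fit <- fit_svm_sgd(Xtr, ytr, alpha = config$svm_alpha,
                       epochs = config$svm_epochs, seed = seed)
    list(score = predict_svm_score(fit, Xte), cut = 0, fit = fit)
  } else {
    fit <- fit_rf(Xtr, ytr, num_trees = config$rf_num_trees, seed = seed,
                  probability = TRUE)
    list(score = predict_rf_score(fit, Xte, levels(ytr)[2L]), cut = 0.5,
         fit = fit)
  }
}

# Stratified k-fold cross-validation accuracy. LR folds warm-start from the
# full-training fit, which only changes the optimisation path length, not
# the optimum.
cv_accuracy <- function(X, y, config, k, seed, warm = NULL) {
  folds <- withr::with_seed(seed, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  correct <- vapply(seq_len(k), function(fold) {
    hold <- which(folds == fold)
    if (!length(hold)) return(c(0, 0))
    fit_idx <- which(folds != fold)
    sc <- model_scores(X[fit_idx, , drop = FALSE], droplevels(y[fit_idx]),
                       X[hold, , drop = FALSE], config,
                       derive_seed(seed, fold), warm = warm)
    pred <- ifelse(sc$score > sc$cut, levels(y)[2L], levels(y)[1L])
    c(sum(pred == as.character(y[hold])), length(hold))
  }, numeric(2))
  sum(correct[1L, ]) / sum(correct[2L, ])
}

f1_score <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("<metrics_summary> %s over %d iterations: ROC AUC %.4f | F1 %.4f | CV %.4f | accuracy %.4f\n",
              x$method, x$n_iterations, x$mean_roc_auc, x$mean_f1,
              x$mean_cv_accuracy, x$mean_accuracy))
  invisible(x)
}

#' Tabulate metric summaries
#'
#' One row per method in input order, metric columns in the order ROC AUC,
#' F1-score, cross-validation accuracy, accuracy, rounded to 4 decimals.
#'
#' @param summaries list of `metrics_summary` objects (may be empty).
#' @param path optional TSV output path.
#' @return A data frame with columns `method`, `roc_auc`, `f1_score`,
#'   `cross_validation`, `accuracy`.
#' @export
metrics_report <- function(summaries, path = NULL) {
  stopifnot(all(vapply(summaries, inherits, TRUE, "metrics_summary")))
  if (!length(summaries)) {
    out <- data.frame(method = character(0), roc_auc = numeric(0),
                      f1_score = numeric(0), cross_validation = numeric(0),
                      accuracy = numeric(0))
  } else {
    out <- data.frame(
      method = vapply(summaries, `[[`, "", "method"),
      roc_auc = round(vapply(summaries, `[[`, 0, "mean_roc_auc"), 4L),
      f1_score = round(vapply(summaries, `[[`, 0, "mean_f1"), 4L),
      cross_validation = round(vapply(summaries, `[[`, 0, "mean_cv_accuracy"), 4L),
      accuracy = round(vapply(summaries, `[[`, 0, "mean_accuracy"), 4L)
    )
  }
  if (!is.null(path)) {
    utils::write.table(format(out, nsmall = 4L), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
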