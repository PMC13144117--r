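test_that("all metrics are exactly one in the separable limit", {
  pg <- separable_pg()
  for (m in c("lr", "svm", "rf")) {
    # extra SGD epochs: at 40 genomes a fold holds ~7 samples and the hinge
    # fit must be converged tightly for every one of them
    s <- evaluate_method(pg, selector_config(m, svm_epochs = 150L, seed = 5),
                         n_iterations = 5, cv_folds = 5)
    tab <- s$per_iteration_table
    expect_true(all(tab$roc_auc == 1), label = paste(m, "ROC AUC"))
    expect_true(all(tab$f1 == 1), label = paste(m, "F1"))
    expect_true(all(tab$cv_accuracy == 1), label = paste(m, "CV accuracy"))
    expect_true(all(tab$accuracy == 1), label = paste(m, "accuracy"))
  }
})

test_that("summary means equal the per-iteration averages", {
  pg <- generate_pangenome(synthetic_spec(15, 15, n_core = 10, n_cloud = 60,
                                          n_markers = 5, p_marker_a = 0.9,
                                          p_marker_b = 0.1, flip_noise = 0.05,
                                          seed = 2))
  s <- evaluate_method(pg, selector_config("rf", seed = 4), n_iterations = 6,
                       cv_folds = 3)
  tab <- s$per_iteration_table
  expect_equal(s$mean_roc_auc, mean(tab$roc_auc), tolerance = 1e-12)
  expect_equal(s$mean_f1, mean(tab$f1), tolerance = 1e-12)
  expect_equal(s$mean_cv_accuracy, mean(tab$cv_accuracy), tolerance = 1e-12)
  expect_equal(s$mean_accuracy, mean(tab$accuracy), tolerance = 1e-12)
  expect_true(all(unlist(tab[, -1]) >= 0 & unlist(tab[, -1]) <= 1))
})

test_that("evaluation is deterministic under its seed", {
  pg <- separable_pg(12, 12, n_markers = 4, n_core = 5, n_cloud = 30)
  s1 <- evaluate_method(pg, selector_config("svm", seed = 11),
                        n_iterations = 2, cv_folds = 3)
  s2 <- evaluate_method(pg, selector_config("svm", seed = 11),
                        n_iterations = 2, cv_folds = 3)
  expect_identical(s1, s2)
})

test_that("permuted labels give chance-level ROC AUC", {
  pg <- generate_pangenome(synthetic_spec(30, 30, n_core = 20, n_cloud = 180,
                                          n_markers = 10, p_marker_a = 0.9,
                                          p_marker_b = 0.1, seed = 3))
  aucs <- vapply(1:3, function(rep) {
    nl <- permute_labels(pg, 70 + rep)
    evaluate_method(nl, selector_config("lr", seed = rep),
                    n_iterations = 10, cv_folds = 2)$mean_roc_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("evaluation refuses undersized groups", {
  pg <- separable_pg(5, 5, n_markers = 2, n_core = 5, n_cloud = 10)
  expect_error(evaluate_method(pg, selector_config("rf")), "at least 10")
})

test_that("the metrics table keeps method order and fixed formatting", {
  mk <- function(method, val) {
    structure(list(method = method, mean_roc_auc = val, mean_f1 = val,
                   mean_cv_accuracy = val, mean_accuracy = val,
                   n_iterations = 1L,
                   per_iteration_table = data.frame(iteration = 1L,
                                                    roc_auc = val, f1 = val,
                                                    cv_accuracy = val,
                                                    accuracy = val)),
              class = "metrics_summary")
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- metrics_report(list(mk("lr", 1), mk("svm", 0.97531),
                             mk("rf", 0.5)), path)
  expect_identical(out$method, c("lr", "svm", "rf"))
  expect_equal(out$roc_auc, c(1, 0.9753, 0.5))
  lines <- readLines(path)
  expect_match(lines[2], "1.0000\t1.0000\t1.0000\t1.0000", fixed = TRUE)

  empty <- metrics_report(list(), path)
  expect_equal(nrow(empty), 0L)
  expect_length(readLines(path), 1L)
})
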