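test_that("per-iteration rules follow their documented contracts", {
  rf_cfg <- selector_config("rf")
  svm_cfg <- selector_config("svm")

  imp <- setNames(c(0, 0.7, 0.3, 0), paste0("f", 1:4))
  expect_setequal(per_iteration_select(imp, rf_cfg), c("f2", "f3"))
  expect_identical(per_iteration_select(setNames(numeric(4), paste0("f", 1:4)),
                                        rf_cfg), character(0))

  equal_w <- setNames(rep(2, 50), paste0("f", 1:50))
  expect_identical(per_iteration_select(equal_w, svm_cfg), character(0))

  w <- withr::with_seed(1, setNames(c(rnorm(999, 0, 1e-3), 10),
                                    paste0("f", 1:1000)))
  expect_identical(per_iteration_select(w, svm_cfg), "f1000")

  expect_error(per_iteration_select(imp, selector_config("lr")), "rf and svm")
})

test_that("appearance-frequency retention applies the inclusive threshold", {
  universe <- paste0("f", 1:5)
  sets <- c(replicate(45, c("f1", "f2"), simplify = FALSE),
            replicate(39, "f2", simplify = FALSE),
            replicate(16, character(0), simplify = FALSE))
  # f1 in 45/100 iterations, f2 in 84/100
  log <- fake_iteration_log(sets, universe)
  sel <- stability_retain(log, 0.40)
  expect_setequal(sel$retained, c("f1", "f2"))
  expect_equal(unname(sel$appearance_frequency[c("f1", "f2", "f3")]),
               c(0.45, 0.84, 0))

  # 39/100 is below the bar
  log39 <- fake_iteration_log(c(replicate(39, "f1", simplify = FALSE),
                                replicate(61, character(0), simplify = FALSE)),
                              universe)
  expect_identical(stability_retain(log39, 0.40)$retained, character(0))

  # boundary: threshold 1 retains only ever-present families
  log_all <- fake_iteration_log(replicate(10, "f3", simplify = FALSE),
                                universe)
  expect_identical(stability_retain(log_all, 1)$retained, "f3")
})

test_that("retention frequencies equal brute-force counting", {
  universe <- paste0("f", 1:200)
  sets <- withr::with_seed(4, replicate(30, sample(universe, rpois(1, 20)),
                                        simplify = FALSE))
  sel <- stability_retain(fake_iteration_log(sets, universe), 0.25)
  brute <- vapply(universe, function(f) {
    sum(vapply(sets, function(s) f %in% s, logical(1))) / length(sets)
  }, numeric(1))
  expect_equal(sel$appearance_frequency, brute)
  expect_setequal(sel$retained, names(brute)[brute >= 0.25])
})

test_that("retained sets shrink as the appearance threshold grows", {
  universe <- paste0("f", 1:100)
  sets <- withr::with_seed(5, replicate(40, sample(universe, 25),
                                        simplify = FALSE))
  log <- fake_iteration_log(sets, universe)
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(th) {
    length(stability_retain(log, th)$retained)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("LR contribution retention implements both readings", {
  coefs <- setNames(c(0.5, 0.5, 0), paste0("f", 1:3))
  res <- lr_contribution_retain(coefs, 0.003, "individual_share")
  expect_setequal(res$retained, c("f1", "f2"))
  expect_equal(unname(res$share), c(0.5, 0.5, 0))

  coefs <- setNames(c(10, rep(0.001, 999)), paste0("f", 1:1000))
  res <- lr_contribution_retain(coefs, 0.003, "cumulative_prefix")
  expect_identical(res$retained, "f1")

  res <- lr_contribution_retain(setNames(numeric(3), paste0("f", 1:3)))
  expect_identical(res$retained, character(0))

  # shares sum to one, so at most floor(1/threshold) families can qualify
  for (seed in 1:5) {
    coefs <- withr::with_seed(seed, setNames(rnorm(5000), paste0("f", 1:5000)))
    res <- lr_contribution_retain(coefs, 0.003, "individual_share")
    expect_lte(length(res$retained), floor(1 / 0.003))
    expect_equal(sum(res$share), 1)
  }
})

test_that("external iterations are reproducible and respect the universe", {
  pg <- separable_pg(10, 10, n_markers = 5, n_core = 10, n_cloud = 50)
  cfg <- selector_config("rf", external_iterations = 4, seed = 13)
  log1 <- run_external_iterations(pg, cfg)
  log2 <- run_external_iterations(pg, cfg)
  expect_identical(log1, log2)
  sel <- stability_retain(log1, 0.4)
  union_sel <- unique(unlist(lapply(log1, `[[`, "selected_families")))
  expect_true(all(sel$retained %in% union_sel))
  expect_true(all(union_sel %in% family_ids(pg)))
})

test_that("a single forest refit on separable data finds planted markers", {
  pg <- separable_pg()
  log <- run_external_iterations(pg, selector_config("rf",
                                                     external_iterations = 1,
                                                     seed = 9))
  expect_length(log, 1L)
  expect_true(any(grepl("^marker_", log[[1]]$selected_families)))
})

test_that("the permutation gate silences label-noise refits", {
  pg <- generate_pangenome(synthetic_spec(30, 30, n_core = 20, n_cloud = 280,
                                          n_markers = 0, seed = 4))
  sel <- select_features(pg, selector_config("rf", external_iterations = 10,
                                             seed = 2))
  expect_lte(length(sel$retained), 2L)
  gate <- vapply(sel$iterations, `[[`, logical(1), "gate_passed")
  expect_lt(mean(gate), 0.4)
})

test_that("SGD hinge weights agree with an exact linear SVM on markers", {
  skip_if_not_installed("e1071")
  pg <- separable_pg(30, 30, n_markers = 8, n_core = 10, n_cloud = 60,
                     seed = 12)
  X <- pg$presence
  storage.mode(X) <- "double"
  ours <- pangsel:::fit_svm_sgd(X, pg$labels, seed = 3)
  exact <- e1071::svm(x = X, y = pg$labels, kernel = "linear", scale = FALSE)
  w_exact <- setNames(drop(crossprod(exact$coefs, exact$SV)), colnames(X))
  top_ours <- names(sort(abs(ours$weights), decreasing = TRUE))[1:8]
  top_exact <- names(sort(abs(w_exact), decreasing = TRUE))[1:8]
  expect_setequal(top_ours, planted_truth(synthetic_spec(
    30, 30, n_core = 10, n_cloud = 60, n_markers = 8,
    p_marker_a = 1, p_marker_b = 0, flip_noise = 0, seed = 12)))
  expect_setequal(top_ours, top_exact)
})

test_that("LR selection recovers separating families on easy data", {
  pg <- separable_pg(15, 15, n_markers = 5, n_core = 10, n_cloud = 30)
  sel <- lr_select(pg, selector_config("lr", seed = 2))
  expect_true(all(sprintf("marker_%04d", 1:5) %in% sel$retained))
  expect_s3_class(sel, "method_selection")
  expect_equal(sum(sel$appearance_frequency), 1, tolerance = 1e-12)
})

test_that("selection TSV and iteration log exports round-trip the counts", {
  pg <- separable_pg(10, 10, n_markers = 3, n_core = 5, n_cloud = 20,
                     seed = 6)
  sel <- select_features(pg, selector_config("rf", external_iterations = 3,
                                             seed = 5))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_selection_tsv(sel, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), length(family_ids(pg)))
  expect_setequal(tab$family_id[tab$retained == 1], sel$retained)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_iteration_log(sel$iterations, jl)
  lines <- readLines(jl)
  expect_length(lines, 3L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$iteration, 1L)
})
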