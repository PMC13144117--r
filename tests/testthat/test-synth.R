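test_that("degenerate probabilities give deterministic matrices", {
  spec <- synthetic_spec(2, 2, n_core = 1, n_cloud = 0, n_markers = 0,
                         p_core = 1, flip_noise = 0, seed = 1)
  pg <- generate_pangenome(spec)
  expect_equal(dim(pg$presence), c(4L, 1L))
  expect_true(all(pg$presence == 1L))

  spec <- synthetic_spec(50, 50, n_core = 0, n_cloud = 0, n_markers = 10,
                         p_marker_a = 1, p_marker_b = 0, flip_noise = 0,
                         seed = 2)
  pg <- generate_pangenome(spec)
  indicator <- as.integer(pg$labels == "A")
  for (f in planted_truth(spec)) {
    expect_equal(unname(pg$presence[, f]), indicator)
    # point-biserial correlation with the label is exactly 1
    expect_equal(cor(pg$presence[, f], indicator), 1)
  }
})

test_that("core-family fill matches its Bernoulli rate", {
  spec <- synthetic_spec(100, 100, n_core = 500, n_cloud = 0, n_markers = 0,
                         p_core = 0.99, seed = 7)
  pg <- generate_pangenome(spec)
  n_cells <- 200 * 500
  se <- sqrt(0.99 * 0.01 / n_cells)
  expect_lt(abs(mean(pg$presence) - 0.99), 3 * se)
})

test_that("generation is bit-reproducible and ordered core/markers/cloud", {
  spec <- scenario_spec(seed = 11)
  pg1 <- generate_pangenome(spec)
  pg2 <- generate_pangenome(spec)
  expect_identical(pg1$presence, pg2$presence)
  expect_identical(pg1$labels, pg2$labels)
  fam <- family_ids(pg1)
  expect_identical(fam, c(sprintf("core_%04d", 1:500),
                          sprintf("marker_%04d", 1:50),
                          sprintf("cloud_%04d", 1:2000)))
  expect_identical(pg1$labels[1:100], setNames(factor(rep("A", 100),
                                                      levels = c("A", "B")),
                                               genome_ids(pg1)[1:100]))
})

test_that("planted truth matches generated marker columns", {
  expect_identical(planted_truth(synthetic_spec(5, 5, n_markers = 0)),
                   character(0))
  spec <- synthetic_spec(5, 5, n_core = 3, n_cloud = 4, n_markers = 10,
                         seed = 4)
  truth <- planted_truth(spec)
  expect_length(truth, 10)
  pg <- generate_pangenome(spec)
  expect_true(all(truth %in% family_ids(pg)))
  expect_false(any(truth %in% grep("^(core|cloud)", family_ids(pg),
                                   value = TRUE)))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(-1, 5), "n_genomes_a")
  expect_error(synthetic_spec(5, 5, p_core = 1.2), "p_core")
  expect_error(synthetic_spec(5, 5, flip_noise = -0.1), "flip_noise")
  expect_error(synthetic_spec(5, 5, n_core = 0, n_cloud = 0, n_markers = 0),
               "at least one gene family")
})

test_that("group-wise presence counts are invariant to genome order", {
  pg <- generate_pangenome(synthetic_spec(15, 25, n_core = 10, n_cloud = 40,
                                          n_markers = 5, seed = 9))
  perm <- withr::with_seed(1, sample(40))
  shuffled <- new_pangenome(pg$presence[perm, ], pg$labels[perm])
  for (lv in c("A", "B")) {
    expect_equal(colSums(shuffled$presence[shuffled$labels == lv, ]),
                 colSums(pg$presence[pg$labels == lv, ]))
  }
})

test_that("synthetic export hides roles behind aliases with a truth sidecar", {
  spec <- synthetic_spec(5, 5, n_core = 3, n_cloud = 4, n_markers = 2,
                         seed = 21)
  pg <- generate_pangenome(spec)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_pangenome(pg, spec, dir)
  back <- read_rtab(paths$matrix)
  expect_false(any(grepl("core|marker|cloud", family_ids(back))))
  expect_equal(unname(back$presence),
               unname(pg$presence))
  amap <- read.delim(paths$alias_map)
  truth_alias <- readLines(paths$truth)
  expect_setequal(amap$family_id[match(truth_alias, amap$alias)],
                  planted_truth(spec))
  labs <- read_labels(paths$labels)
  expect_equal(labs$group, as.character(pg$labels))
})
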