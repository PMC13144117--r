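test_that("set algebra over three selections is exact", {
  universe <- paste0("g", 1:4)
  cons <- build_consensus(list(
    fake_selection("lr", c("g1", "g2"), universe),
    fake_selection("svm", c("g2", "g3"), universe),
    fake_selection("rf", "g2", universe)))
  expect_identical(cons$venn_regions[["lr_svm_rf"]], "g2")
  expect_setequal(cons$union, c("g1", "g2", "g3"))
  expect_identical(cons$venn_regions[["lr_only"]], "g1")
  expect_identical(cons$venn_regions[["svm_only"]], "g3")
  expect_equal(unname(cons$per_method_counts), c(2L, 2L, 1L))

  empty <- build_consensus(lapply(c("lr", "svm", "rf"), fake_selection,
                                  retained = character(0),
                                  universe = universe))
  expect_true(all(lengths(empty$venn_regions) == 0))
})

test_that("Venn regions match exhaustive per-family enumeration", {
  universe <- sprintf("fam%05d", 1:30000)
  sets <- withr::with_seed(3, list(lr = sample(universe, 1047),
                                   svm = sample(universe, 85),
                                   rf = sample(universe, 113)))
  cons <- build_consensus(list(fake_selection("lr", sets$lr, universe),
                               fake_selection("svm", sets$svm, universe),
                               fake_selection("rf", sets$rf, universe)))
  membership <- vapply(universe, function(f) {
    paste0(as.integer(f %in% sets$lr), as.integer(f %in% sets$svm),
           as.integer(f %in% sets$rf))
  }, character(1))
  oracle <- table(membership)
  cnt <- function(code) {
    if (is.na(oracle[code])) 0L else as.integer(oracle[code])
  }
  expect_equal(length(cons$venn_regions[["lr_only"]]), cnt("100"))
  expect_equal(length(cons$venn_regions[["svm_only"]]), cnt("010"))
  expect_equal(length(cons$venn_regions[["rf_only"]]), cnt("001"))
  expect_equal(length(cons$venn_regions[["lr_svm"]]), cnt("110"))
  expect_equal(length(cons$venn_regions[["lr_rf"]]), cnt("101"))
  expect_equal(length(cons$venn_regions[["svm_rf"]]), cnt("011"))
  expect_equal(length(cons$venn_regions[["lr_svm_rf"]]), cnt("111"))
  # the regions partition the union
  all_regions <- unlist(cons$venn_regions)
  expect_equal(anyDuplicated(all_regions), 0L)
  expect_setequal(all_regions, cons$union)
})

test_that("consensus rejects malformed inputs", {
  universe <- paste0("g", 1:4)
  sels <- lapply(c("lr", "svm", "rf"), fake_selection,
                 retained = "g1", universe = universe)
  expect_error(build_consensus(sels[1:2]), "three")
  sels2 <- sels
  sels2[[2]] <- fake_selection("svm", "x1", paste0("x", 1:4))
  expect_error(build_consensus(sels2), "universes")
  sels3 <- sels
  sels3[[2]]$method <- "lr"
  expect_error(build_consensus(sels3), "distinct")
})

test_that("deduplication collapses identical sequences to the smallest ID", {
  res <- deduplicate(c("f1", "f2", "f3"))
  expect_identical(res$families, c("f1", "f2", "f3"))
  expect_length(res$dedup_map, 0L)

  res <- deduplicate(c("f1", "f2", "f3"),
                     c(f1 = "MKV", f2 = "MKV", f3 = "MA"))
  expect_identical(res$families, c("f1", "f3"))
  expect_identical(res$dedup_map, c(f2 = "f1"))

  expect_error(deduplicate(c("f1", "f9"), c(f1 = "MKV")), "f9")
})

test_that("deduplication matches a hash-bucket oracle and is idempotent", {
  ids <- sprintf("fam%03d", 1:100)
  seqs <- withr::with_seed(8, {
    base <- vapply(1:60, function(i) {
      paste(sample(c("M", "K", "V", "A", "L"), 12, replace = TRUE),
            collapse = "")
    }, character(1))
    # 40 families duplicated pairwise onto the first 40 base sequences
    setNames(c(base, base[1:40]), ids)
  })
  res <- deduplicate(ids, seqs)
  oracle_survivors <- vapply(split(ids, unname(seqs)),
                             function(x) sort(x)[1], character(1))
  expect_length(res$families, 60L)
  expect_setequal(res$families, unname(oracle_survivors))
  twice <- deduplicate(res$families, seqs)
  expect_identical(twice$families, res$families)
  expect_length(twice$dedup_map, 0L)
  expect_lte(length(res$families), length(ids))
})
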