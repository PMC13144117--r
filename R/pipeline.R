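#' Configure an end-to-end pipeline run
#'
#' Exactly one input source must be given: either a presence/absence matrix
#' on disk (`matrix_path`, Rtab or CSV, plus `labels_path`) or a synthetic
#' block (`synthetic`, a [synthetic_spec()]). A single global seed fans out
#' deterministically to per-stage and per-iteration seeds, so one number
#' reproduces the whole run.
#'
#' @param out_dir output directory (created if needed).
#' @param matrix_path optional path to an Rtab (`.Rtab`/`.tsv`) or CSV
#'   presence matrix.
#' @param labels_path label TSV, required with `matrix_path`.
#' @param synthetic optional [synthetic_spec()].
#' @param annotations_path optional eggNOG-mapper annotation TSV for the COG
#'   summary stage.
#' @param sequences_path optional protein FASTA for consensus deduplication.
#' @param external_iterations,appearance_threshold stability-selection
#'   settings shared by the rf and svm selectors.
#' @param eval_iterations,test_fraction,cv_folds evaluation settings; set
#'   `eval_iterations = 0` to skip evaluation.
#' @param seed global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            matrix_path = NULL, labels_path = NULL,
                            synthetic = NULL,
                            annotations_path = NULL, sequences_path = NULL,
                            external_iterations = 100L,
                            appearance_threshold = 0.40,
                            eval_iterations = 100L,
                            test_fraction = 0.1, cv_folds = 10L,
                            seed = 1L) {
  if (is.null(matrix_path) == is.null(synthetic)) {
    stop("exactly one of `matrix_path` or `synthetic` must be given",
         call. = FALSE)
  }
  if (!is.null(matrix_path) && is.null(labels_path)) {
    stop("`labels_path` is required with `matrix_path`", call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "pangenome_spec"))
  structure(list(out_dir = out_dir, matrix_path = matrix_path,
                 labels_path = labels_path, synthetic = synthetic,
                 annotations_path = annotations_path,
                 sequences_path = sequences_path,
                 external_iterations = check_count(external_iterations,
                                                   "external_iterations",
                                                   min = 1L),
                 appearance_threshold = check_fraction(appearance_threshold,
                                                       "appearance_threshold",
                                                       allow_zero = FALSE),
                 eval_iterations = check_count(eval_iterations,
                                               "eval_iterations"),
                 test_fraction = check_fraction(test_fraction,
                                                "test_fraction",
                                                allow_zero = FALSE,
                                                allow_one = FALSE),
                 cv_folds = check_count(cv_folds, "cv_folds", min = 2L),
                 seed = check_count(seed, "seed")),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; a `synthetic:` mapping is
#' passed to [synthetic_spec()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_spec, y$synthetic)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes input (synthetic generation or matrix reading) -> exploratory
#' PCA/clustering -> the three selectors (lr, svm, rf) -> consensus ->
#' evaluation -> COG annotation summary (when annotations are given), writing
#' every stage's outputs plus a `manifest.json` (configuration echo, derived
#' stage seeds, versions, per-stage counts) under `config$out_dir`. Any stage
#' error aborts the run naming the stage.
#'
#' @param config a [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the pangenome, PCA result, selections,
#'   consensus, metric summaries and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_line <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  pg <- stage("input", {
    if (!is.null(config$synthetic)) {
      g <- generate_pangenome(config$synthetic)
      write_synthetic_pangenome(g, config$synthetic, file.path(out, "input"))
      g
    } else {
      reader <- if (grepl("\\.csv$", config$matrix_path, ignore.case = TRUE)) {
        read_presence_csv
      } else {
        read_rtab
      }
      attach_labels(reader(config$matrix_path), config$labels_path)
    }
  })
  log_line("input", sprintf("%d genomes x %d families",
                            nrow(pg$presence), ncol(pg$presence)))

  pca <- stage("explore", {
    p <- run_pca(pg)
    write_pca_tsv(p, file.path(out, "pca_cumulative_variance.tsv"),
                  file.path(out, "pca_projection.tsv"))
    k <- elbow_select_k(p$projection_2d, 1L,
                        min(8L, nrow(p$projection_2d)),
                        seed = derive_seed(config$seed, 2L))
    cl <- cluster_genomes(p$projection_2d, k,
                          seed = derive_seed(config$seed, 3L))
    utils::write.table(
      data.frame(genome_id = names(cl), cluster = cl),
      file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    p$elbow_k <- k
    p
  })
  log_line("explore", sprintf("%d components for 90%% variance; elbow k = %d",
                              pca$n_components_90, pca$elbow_k))

  method_seeds <- c(lr = derive_seed(config$seed, 11L),
                    svm = derive_seed(config$seed, 12L),
                    rf = derive_seed(config$seed, 13L))
  selections <- stage("selectors", {
    lapply(setNames(nm = c("lr", "svm", "rf")), function(m) {
      cfg <- selector_config(
        method = m,
        external_iterations = config$external_iterations,
        appearance_threshold = config$appearance_threshold,
        seed = method_seeds[[m]])
      sel <- select_features(pg, cfg)
      write_selection_tsv(sel, file.path(out, sprintf("selection_%s.tsv", m)))
      if (!is.null(sel$iterations)) {
        write_iteration_log(sel$iterations,
                            file.path(out, sprintf("iterations_%s.jsonl", m)))
      }
      sel
    })
  })
  for (m in names(selections)) {
    log_line("selectors", sprintf("%s retained %d families", m,
                                  length(selections[[m]]$retained)))
  }

  consensus <- stage("consensus", {
    seqs <- if (!is.null(config$sequences_path)) {
      read_protein_fasta(config$sequences_path)
    }
    cs <- build_consensus(unname(selections), sequences = seqs)
    write_venn_tsv(cs, file.path(out, "venn_counts.tsv"))
    writeLines(cs$union_nonredundant, file.path(out, "union_nonredundant.txt"))
    cs
  })

  summaries <- if (config$eval_iterations > 0L) {
    stage("evaluate", {
      ss <- lapply(setNames(nm = c("lr", "svm", "rf")), function(m) {
        s <- evaluate_method(pg,
                             selector_config(method = m,
                                             seed = method_seeds[[m]]),
                             n_iterations = config$eval_iterations,
                             test_fraction = config$test_fraction,
                             cv_folds = config$cv_folds)
        tab <- s$per_iteration_table
        writeLines(vapply(seq_len(nrow(tab)), function(i) {
          jsonlite::toJSON(as.list(tab[i, ]), auto_unbox = TRUE, digits = NA)
        }, character(1)), file.path(out, sprintf("metrics_%s.jsonl", m)))
        s
      })
      metrics_report(unname(ss), path = file.path(out, "metrics.tsv"))
      ss
    })
  } else {
    list()
  }

  cogs <- if (!is.null(config$annotations_path)) {
    stage("annotate", {
      recs <- read_emapper(config$annotations_path)
      dists <- c(lapply(selections, function(s) {
        cog_distribution(recs, subset = s$retained)
      }), list(union = cog_distribution(recs, subset = consensus$union_nonredundant)))
      write_cog_tsv(dists, file.path(out, "cog_distribution.tsv"))
      dists
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pangsel")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    method_seeds = as.list(method_seeds),
    n_genomes = nrow(pg$presence),
    n_families = ncol(pg$presence),
    n_components_90 = pca$n_components_90,
    elbow_k = pca$elbow_k,
    per_method_retained = lapply(selections, function(s) length(s$retained)),
    venn_region_counts = as.list(lengths(consensus$venn_regions)),
    union_size = length(consensus$union),
    union_nonredundant_size = length(consensus$union_nonredundant),
    metrics = if (length(summaries)) {
      lapply(summaries, function(s) {
        list(roc_auc = s$mean_roc_auc, f1 = s$mean_f1,
             cross_validation = s$mean_cv_accuracy,
             accuracy = s$mean_accuracy)
      })
    },
    config = config[!vapply(config, is.null, TRUE)]
  )
  manifest$config$synthetic <- if (!is.null(config$synthetic)) {
    unclass(config$synthetic)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(pangenome = pg, pca = pca, selections = selections,
                 consensus = consensus, metrics = summaries, cog = cogs,
                 manifest = manifest))
}
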