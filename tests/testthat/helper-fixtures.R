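# Shared fixture builders. Everything is generated in code; no data files.

# Small labeled pangenome with perfectly separating markers.
separable_pg <- function(n_a = 20L, n_b = 20L, n_markers = 10L,
                         n_core = 20L, n_cloud = 100L, seed = 3L) {
  generate_pangenome(synthetic_spec(
    n_a, n_b, n_core = n_core, n_cloud = n_cloud, n_markers = n_markers,
    p_marker_a = 1, p_marker_b = 0, flip_noise = 0, seed = seed))
}

# The planted-marker study scenario used by the acceptance checks.
scenario_spec <- function(seed = 42L) {
  synthetic_spec(100L, 100L, n_core = 500L, n_cloud = 2000L, n_markers = 50L,
                 p_marker_a = 0.95, p_marker_b = 0.05, flip_noise = 0.01,
                 seed = seed)
}

# Permute a pangenome's labels (fixed permutation null).
permute_labels <- function(pg, seed) {
  perm <- withr::with_seed(seed, sample(nrow(pg$presence)))
  new_pangenome(pg$presence,
                stats::setNames(as.character(pg$labels)[perm],
                                rownames(pg$presence)))
}

# Hand-built iteration log for testing retention arithmetic without fits.
fake_iteration_log <- function(selected_sets, universe, method = "rf") {
  records <- lapply(seq_along(selected_sets), function(i) {
    list(iteration = i, selected_families = selected_sets[[i]],
         importance = stats::setNames(numeric(length(universe)), universe),
         gate_ratio = Inf, gate_passed = TRUE, subsample_seed = i)
  })
  structure(records, class = "iteration_log", family_universe = universe,
            method = method,
            config = selector_config(method, external_iterations =
                                       max(1L, length(selected_sets))))
}

# Minimal method_selection over a universe, for consensus tests.
fake_selection <- function(method, retained, universe) {
  structure(list(method = method,
                 appearance_frequency =
                   stats::setNames(as.numeric(universe %in% retained),
                                   universe),
                 retained = retained,
                 config_echo = NULL),
            class = "method_selection")
}

# Write an emapper-style annotation file; rows = list of c(query, evalue,
# cog, description). Returns the path.
write_emapper_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                                  header = TRUE) {
  lines <- c("## emapper-like output",
             if (header)
               paste0("#", paste(c("query", "seed_ortholog", "evalue",
                                   "score", "eggNOG_OGs", "max_annot_lvl",
                                   "COG_category", "Description"),
                                 collapse = "\t")))
  for (r in rows) {
    lines <- c(lines, paste(c(r[1], "ortho", r[2], "100", "OG@1", "root",
                              r[3], r[4]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

random_cog_records <- function(n, seed) {
  withr::with_seed(seed, {
    cats <- c("S", "J", "L", "K", "E", "M", "C", "G", "P", "T")
    data.frame(
      query_id = sprintf("q%04d", seq_len(n)),
      evalue = 10^-runif(n, 5, 50),
      cog_letters = vapply(seq_len(n), function(i) {
        paste(sample(cats, sample(0:3, 1)), collapse = "")
      }, character(1)),
      description = sample(c("hypothetical protein", "DNA gyrase",
                             "ABC transporter"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
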