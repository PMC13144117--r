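#' Deduplicate a family set
#'
#' Without sequences, family IDs are already unique cluster representatives
#' and deduplication is the identity. With a sequence map, families whose
#' protein sequences are byte-identical collapse to the lexicographically
#' smallest family ID (C locale), and the mapping from dropped IDs to their
#' representative is returned.
#'
#' @param families character vector of family IDs.
#' @param sequences optional named character vector mapping every family in
#'   `families` to its protein sequence.
#' @return List with `families` (non-redundant, in input order) and
#'   `dedup_map` (named character: dropped ID -> representative).
#' @export
deduplicate <- function(families, sequences = NULL) {
  families <- as.character(families)
  if (is.null(sequences)) {
    return(list(families = families,
                dedup_map = setNames(character(0), character(0))))
  }
  missing <- setdiff(families, names(sequences))
  if (length(missing)) {
    stop("sequence map is missing family(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seqs <- sequences[families]
  rep_of <- vapply(split(families, unname(seqs)),
                   function(ids) sort_c(ids)[1L], character(1))
  reps <- unname(rep_of[unname(seqs)])
  keep <- families == reps
  dropped <- families[!keep]
  list(families = families[keep],
       dedup_map = setNames(reps[!keep], dropped))
}

#' Combine three method selections into a consensus
#'
#' Computes all seven Venn regions of the three retained sets by set algebra
#' over the shared family universe, the per-method counts, and the
#' deduplicated union (see [deduplicate()]).
#'
#' @param selections list of exactly three `method_selection` objects over
#'   the same family universe, with distinct method tags.
#' @param sequences optional named protein sequences covering the union, for
#'   sequence-identity deduplication.
#' @return An object of class `consensus_result` with `per_method_counts`,
#'   `venn_regions` (7 disjoint family-ID sets named by the methods they
#'   belong to exclusively, e.g. `"lr_only"`, `"lr_rf"`, `"lr_rf_svm"`),
#'   `union`, `union_nonredundant` and `dedup_map`.
#' @export
build_consensus <- function(selections, sequences = NULL) {
  if (length(selections) != 3L ||
      !all(vapply(selections, inherits, TRUE, "method_selection"))) {
    stop("`selections` must be a list of exactly three method_selection objects",
         call. = FALSE)
  }
  methods <- vapply(selections, `[[`, "", "method")
  if (anyDuplicated(methods)) {
    stop("method tags must be distinct, got: ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  universes <- lapply(selections, function(s) sort_c(names(s$appearance_frequency)))
  if (!all(vapply(universes[-1L], identical, TRUE, universes[[1L]]))) {
    stop("selections are over different family universes", call. = FALSE)
  }
  names(selections) <- methods
  sets <- lapply(selections, `[[`, "retained")
  a <- sets[[1L]]; b <- sets[[2L]]; c_ <- sets[[3L]]
  m <- methods
  regions <- list(
    setdiff(a, union(b, c_)),
    setdiff(b, union(a, c_)),
    setdiff(c_, union(a, b)),
    setdiff(intersect(a, b), c_),
    setdiff(intersect(a, c_), b),
    setdiff(intersect(b, c_), a),
    intersect(intersect(a, b), c_)
  )
  names(regions) <- c(paste0(m, "_only"),
                      paste(m[1L], m[2L], sep = "_"),
                      paste(m[1L], m[3L], sep = "_"),
                      paste(m[2L], m[3L], sep = "_"),
                      paste(m[1L], m[2L], m[3L], sep = "_"))
  union_all <- Reduce(union, sets)
  dd <- deduplicate(union_all, sequences)
  structure(list(per_method_counts = setNames(lengths(sets), methods),
                 venn_regions = regions,
                 union = union_all,
                 union_nonredundant = dd$families,
                 dedup_map = dd$dedup_map),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>\n")
  cat("  per-method counts:",
      paste(sprintf("%s=%d", names(x$per_method_counts), x$per_method_counts),
            collapse = ", "), "\n")
  cat(sprintf("  union: %d (%d after dedup); triple intersection: %d\n",
              length(x$union), length(x$union_nonredundant),
              length(x$venn_regions[[7L]])))
  invisible(x)
}

#' Write Venn region counts as TSV
#'
#' @param consensus a `consensus_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_venn_tsv <- function(consensus, path) {
  stopifnot(inherits(consensus, "consensus_result"))
  utils::write.table(
    data.frame(region = names(consensus$venn_regions),
               n_families = lengths(consensus$venn_regions)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
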