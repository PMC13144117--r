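#' Specify a synthetic two-group pangenome
#'
#' Parameterises a simulated gene presence/absence matrix for two genome
#' groups. Families come in three roles: core families present with high
#' probability in both groups, cloud families present sparsely and
#' independently of the group, and planted marker families whose presence
#' probability differs between the groups. After Bernoulli sampling every cell
#' is independently inverted with probability `flip_noise`, a single knob that
#' degrades separability symmetrically.
#'
#' @param n_genomes_a,n_genomes_b genomes in groups A and B.
#' @param n_core,n_cloud,n_markers number of core, cloud and planted marker
#'   families. Defaults (500 core / 2000 cloud) are plumbing choices giving a
#'   sparse matrix of realistic shape at desk scale.
#' @param p_marker_a,p_marker_b presence probability of marker families in
#'   group A and group B.
#' @param p_core presence probability of core families (default 0.99).
#' @param p_cloud presence probability of cloud families (default 0.10).
#' @param flip_noise probability that a sampled cell is inverted.
#' @param seed integer RNG seed; the same spec is bit-reproducible.
#' @return An object of class `pangenome_spec`.
#' @seealso [generate_pangenome()], [planted_truth()]
#' @export
synthetic_spec <- function(n_genomes_a, n_genomes_b,
                           n_core = 500L, n_cloud = 2000L, n_markers = 50L,
                           p_marker_a = 0.95, p_marker_b = 0.05,
                           p_core = 0.99, p_cloud = 0.10,
                           flip_noise = 0, seed = 1L) {
  spec <- list(
    n_genomes_a = check_count(n_genomes_a, "n_genomes_a", min = 1L),
    n_genomes_b = check_count(n_genomes_b, "n_genomes_b", min = 1L),
    n_core = check_count(n_core, "n_core"),
    n_cloud = check_count(n_cloud, "n_cloud"),
    n_markers = check_count(n_markers, "n_markers"),
    p_marker_a = check_fraction(p_marker_a, "p_marker_a"),
    p_marker_b = check_fraction(p_marker_b, "p_marker_b"),
    p_core = check_fraction(p_core, "p_core"),
    p_cloud = check_fraction(p_cloud, "p_cloud"),
    flip_noise = check_fraction(flip_noise, "flip_noise"),
    seed = check_count(seed, "seed")
  )
  if (spec$n_core + spec$n_cloud + spec$n_markers < 1L) {
    stop("at least one gene family is required", call. = FALSE)
  }
  structure(spec, class = "pangenome_spec")
}

#' @export
print.pangenome_spec <- function(x, ...) {
  cat(sprintf(
    "<pangenome_spec> %d+%d genomes; %d core (p=%.2f), %d markers (pA=%.2f, pB=%.2f), %d cloud (p=%.2f); flip_noise=%.3f; seed=%d\n",
    x$n_genomes_a, x$n_genomes_b, x$n_core, x$p_core, x$n_markers,
    x$p_marker_a, x$p_marker_b, x$n_cloud, x$p_cloud, x$flip_noise, x$seed))
  invisible(x)
}

synth_family_ids <- function(spec) {
  c(if (spec$n_core) sprintf("core_%04d", seq_len(spec$n_core)),
    if (spec$n_markers) sprintf("marker_%04d", seq_len(spec$n_markers)),
    if (spec$n_cloud) sprintf("cloud_%04d", seq_len(spec$n_cloud)))
}

#' Generate a labeled synthetic pangenome
#'
#' Draws every cell from a Bernoulli distribution with its family- and
#' group-specific presence probability, then inverts each cell independently
#' with probability `flip_noise`. Columns are ordered core families, then
#' markers, then cloud; the first `n_genomes_a` genomes are labeled "A".
#' Family IDs encode their role (`core_0001`, `marker_0003`, ...) so recovery
#' can be asserted without a side channel; [write_synthetic_pangenome()]
#' exports the matrix under opaque aliases with a truth sidecar instead.
#'
#' @param spec a [synthetic_spec()].
#' @return A labeled [new_pangenome()].
#' @export
generate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "pangenome_spec"))
  n <- spec$n_genomes_a + spec$n_genomes_b
  p <- spec$n_core + spec$n_markers + spec$n_cloud
  fam <- synth_family_ids(spec)
  in_a <- rep(c(TRUE, FALSE), c(spec$n_genomes_a, spec$n_genomes_b))
  prob <- matrix(0, n, p)
  col <- 0L
  if (spec$n_core) {
    prob[, col + seq_len(spec$n_core)] <- spec$p_core
    col <- col + spec$n_core
  }
  if (spec$n_markers) {
    prob[, col + seq_len(spec$n_markers)] <-
      ifelse(in_a, spec$p_marker_a, spec$p_marker_b)
    col <- col + spec$n_markers
  }
  if (spec$n_cloud) prob[, col + seq_len(spec$n_cloud)] <- spec$p_cloud
  m <- withr::with_seed(spec$seed, {
    x <- matrix(rbinom(n * p, 1L, prob), n, p)
    if (spec$flip_noise > 0) {
      flip <- matrix(runif(n * p) < spec$flip_noise, n, p)
      x[flip] <- 1L - x[flip]
    }
    x
  })
  dimnames(m) <- list(sprintf("genome_%04d", seq_len(n)), fam)
  labels <- factor(ifelse(in_a, "A", "B"), levels = c("A", "B"))
  new_pangenome(m, labels)
}

#' Planted marker families of a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return Character vector of the marker family IDs, exactly as they appear
#'   as columns of [generate_pangenome()].
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "pangenome_spec"))
  if (spec$n_markers == 0L) return(character(0))
  sprintf("marker_%04d", seq_len(spec$n_markers))
}

#' Export a synthetic pangenome with opaque family aliases
#'
#' Writes the presence matrix as Rtab under opaque family aliases
#' (`fam_000001`, ...) so the role-encoding IDs never leak into the selection
#' pipeline, plus a genome label TSV, a marker-truth sidecar (one aliased ID
#' per line) and the alias map.
#'
#' @param pangenome a labeled `pangenome` produced by [generate_pangenome()].
#' @param spec the [synthetic_spec()] that produced it.
#' @param dir output directory, created if needed.
#' @return Invisibly, a named list of the four file paths.
#' @export
write_synthetic_pangenome <- function(pangenome, spec, dir) {
  assert_labeled(pangenome)
  stopifnot(inherits(spec, "pangenome_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fam <- family_ids(pangenome)
  alias <- sprintf("fam_%06d", seq_along(fam))
  aliased <- pangenome
  colnames(aliased$presence) <- alias
  paths <- list(
    matrix = file.path(dir, "presence_absence.Rtab"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "marker_truth.txt"),
    alias_map = file.path(dir, "alias_map.tsv")
  )
  write_rtab(aliased, paths$matrix)
  write_labels(pangenome, paths$labels)
  truth <- alias[fam %in% planted_truth(spec)]
  writeLines(truth, paths$truth)
  utils::write.table(
    data.frame(alias = alias, family_id = fam),
    paths$alias_map, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
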