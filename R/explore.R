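#' Exploratory PCA of a presence/absence matrix
#'
#' Principal component analysis on the raw 0/1 matrix with columns
#' mean-centered but not scaled, the standard treatment for presence/absence
#' data. Reports the per-component explained-variance ratio, its running sum,
#' the smallest number of components whose cumulative explained variance
#' reaches `target_variance`, and the projection of the genomes onto the top
#' two components. This stage is exploratory only; its output never feeds
#' feature selection.
#'
#' @param pangenome a `pangenome` (labels optional) with at least 2 genomes
#'   and 2 families.
#' @param target_variance cumulative-variance target (default 0.90).
#' @return An object of class `pca_result` with elements
#'   `explained_variance_ratio`, `cumulative_curve`, `n_components_90` and
#'   `projection_2d`.
#' @export
run_pca <- function(pangenome, target_variance = 0.90) {
  stopifnot(inherits(pangenome, "pangenome"))
  check_fraction(target_variance, "target_variance")
  m <- pangenome$presence
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("PCA needs at least 2 genomes and 2 families", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (all(apply(m, 2L, function(x) x[1L] == x) == TRUE)) {
    stop("no variance: presence matrix is constant", call. = FALSE)
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  var_total <- sum(pc$sdev^2)
  evr <- pc$sdev^2 / var_total
  cum <- cumsum(evr)
  n90 <- which(cum >= target_variance - 1e-12)[1L]
  if (is.na(n90)) n90 <- length(cum)
  proj <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(proj) < 2L) proj <- cbind(proj, 0)
  colnames(proj) <- c("PC1", "PC2")
  structure(list(explained_variance_ratio = evr,
                 cumulative_curve = cum,
                 n_components_90 = as.integer(n90),
                 projection_2d = proj),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; %d needed for %.0f%% variance; PC1+PC2 explain %.1f%%\n",
              length(x$explained_variance_ratio), x$n_components_90,
              100 * x$cumulative_curve[x$n_components_90],
              100 * sum(x$explained_variance_ratio[1:min(2, length(x$explained_variance_ratio))])))
  invisible(x)
}

kmeans_wss <- function(embedding, k, seed) {
  n_distinct <- nrow(unique(embedding))
  if (k >= n_distinct) return(0)
  fit <- withr::with_seed(seed, kmeans(embedding, centers = k, nstart = 10L,
                                       iter.max = 100L))
  fit$tot.withinss
}

#' Choose a cluster count by the elbow method
#'
#' Fits centroid (k-means) clusterings for each k in `[k_min, k_max]`,
#' records the within-cluster dispersion, and returns the k of maximum
#' curvature — the largest second difference of the dispersion curve. Ties go
#' to the smallest k; when the dispersion is zero everywhere (or the range is
#' too narrow to measure curvature) `k_min` is returned.
#'
#' @param embedding numeric matrix of points (e.g. a 2-D PCA projection).
#' @param k_min,k_max inclusive range of cluster counts to consider;
#'   `k_max` must not exceed the number of points.
#' @param seed RNG seed for the k-means restarts.
#' @return The selected integer k.
#' @export
elbow_select_k <- function(embedding, k_min = 1L, k_max, seed = 1L) {
  embedding <- as.matrix(embedding)
  k_min <- check_count(k_min, "k_min", min = 1L)
  k_max <- check_count(k_max, "k_max", min = 1L)
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  if (k_max > nrow(embedding)) {
    stop("k_max exceeds the number of points", call. = FALSE)
  }
  if (k_min == k_max) return(k_min)
  ks <- k_min:k_max
  wss <- vapply(ks, function(k) kmeans_wss(embedding, k, derive_seed(seed, k)),
                numeric(1))
  if (all(wss < 1e-12) || length(ks) < 3L) return(k_min)
  d2 <- wss[-c(length(wss) - 1L, length(wss))] -
    2 * wss[-c(1L, length(wss))] + wss[-(1:2)]
  ks[which.max(d2) + 1L]
}

#' Centroid clustering of an embedding
#'
#' Seeded k-means partition of the points into k clusters. Cluster labels are
#' arbitrary but stable under the seed. `k = 1` (a single cluster) is a
#' supported degenerate input.
#'
#' @inheritParams elbow_select_k
#' @param k number of clusters, `1 <= k <=` number of points.
#' @return Integer vector of cluster assignments named by row.
#' @export
cluster_genomes <- function(embedding, k, seed = 1L) {
  embedding <- as.matrix(embedding)
  k <- check_count(k, "k", min = 1L)
  if (k > nrow(embedding)) {
    stop("k exceeds the number of points", call. = FALSE)
  }
  if (k == 1L) {
    out <- rep(1L, nrow(embedding))
  } else if (k == nrow(embedding)) {
    out <- seq_len(nrow(embedding))
  } else {
    fit <- withr::with_seed(seed, kmeans(embedding, centers = k,
                                         nstart = 10L, iter.max = 100L))
    out <- as.integer(fit$cluster)
  }
  names(out) <- rownames(embedding)
  out
}

#' Write PCA summaries as TSV
#'
#' Emits the cumulative-variance curve and the 2-D projection for external
#' plotting.
#'
#' @param pca a `pca_result`.
#' @param variance_path,projection_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_pca_tsv <- function(pca, variance_path, projection_path) {
  stopifnot(inherits(pca, "pca_result"))
  utils::write.table(
    data.frame(component = seq_along(pca$explained_variance_ratio),
               explained_variance_ratio = pca$explained_variance_ratio,
               cumulative = pca$cumulative_curve),
    variance_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(genome_id = rownames(pca$projection_2d),
               PC1 = pca$projection_2d[, 1L], PC2 = pca$projection_2d[, 2L]),
    projection_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(variance_path, projection_path))
}
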