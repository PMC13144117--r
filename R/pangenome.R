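#' Pangenome presence/absence container
#'
#' A `pangenome` wraps a binary genomes-by-families matrix together with an
#' optional two-level group label per genome. Rows are genomes, columns are
#' gene families; cells are 0 (absent) or 1 (present).
#'
#' @param presence integer or numeric matrix of 0/1 values with genome IDs as
#'   row names and family IDs as column names.
#' @param labels optional factor (or character) of group labels, one per
#'   genome, with exactly two levels when supplied. May be named by genome ID;
#'   unnamed vectors are matched positionally.
#' @return An object of class `pangenome`.
#' @export
new_pangenome <- function(presence, labels = NULL) {
  if (!is.matrix(presence)) stop("`presence` must be a matrix", call. = FALSE)
  if ((nrow(presence) > 0L && is.null(rownames(presence))) ||
      (ncol(presence) > 0L && is.null(colnames(presence)))) {
    stop("`presence` must have genome row names and family column names",
         call. = FALSE)
  }
  # zero-extent margins drop their dimnames in R; restore empty ones
  dimnames(presence) <- list(rownames(presence) %||% character(0),
                             colnames(presence) %||% character(0))
  if (anyDuplicated(rownames(presence))) {
    stop("duplicate genome IDs in presence matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(presence))) {
    stop("duplicate family IDs in presence matrix", call. = FALSE)
  }
  bad <- which(!(presence %in% c(0L, 1L)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(presence)) + 1
    j <- ((bad[1] - 1) %/% nrow(presence)) + 1
    stop(sprintf("non-binary cell %s for family '%s', genome '%s'",
                 format(presence[bad[1]]), colnames(presence)[j],
                 rownames(presence)[i]), call. = FALSE)
  }
  storage.mode(presence) <- "integer"
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      missing <- setdiff(rownames(presence), names(labels))
      if (length(missing)) {
        stop("labels missing for genome(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      labels <- labels[rownames(presence)]
    }
    if (length(labels) != nrow(presence)) {
      stop("`labels` must have one entry per genome", call. = FALSE)
    }
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2L) {
      stop(sprintf("exactly two label levels required, found %d (%s)",
                   nlevels(labels), paste(levels(labels), collapse = ", ")),
           call. = FALSE)
    }
    names(labels) <- rownames(presence)
  }
  structure(list(presence = presence, labels = labels), class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome> %d genomes x %d gene families\n",
              nrow(x$presence), ncol(x$presence)))
  cat(sprintf("  fill: %.1f%% present\n",
              100 * mean(x$presence)))
  if (is.null(x$labels)) {
    cat("  labels: <none>\n")
  } else {
    tab <- table(x$labels)
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname new_pangenome
#' @param x a `pangenome`.
#' @export
genome_ids <- function(x) rownames(x$presence)

#' @rdname new_pangenome
#' @export
family_ids <- function(x) colnames(x$presence)

is_labeled <- function(x) !is.null(x$labels)

assert_labeled <- function(x) {
  if (!inherits(x, "pangenome")) stop("expected a `pangenome`", call. = FALSE)
  if (!is_labeled(x)) {
    stop("pangenome has no labels; call attach_labels() first", call. = FALSE)
  }
  invisible(x)
}
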