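#' COG functional-category distribution
#'
#' Tallies Clusters of Orthologous Groups (COG) category letters over a set
#' of annotation records. A record annotated with several categories (e.g.
#' `"JL"`) contributes fractionally by default — 1/2 to J and 1/2 to L — so
#' the total mass equals the number of annotated records and the percentages
#' sum to 100; `fractional = FALSE` instead counts each letter once. Records
#' with no COG letters are counted as unannotated, as are subset IDs with no
#' record at all.
#'
#' @param records data frame from [read_emapper()].
#' @param subset optional character vector of query IDs to restrict to.
#' @param fractional fractional (default) or whole-count handling of
#'   multi-letter categories.
#' @return An object of class `cog_distribution`: `table` (category, count,
#'   percentage, sorted by decreasing count), `total_annotated`,
#'   `unannotated`.
#' @export
cog_distribution <- function(records, subset = NULL, fractional = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("query_id", "cog_letters") %in% names(records)))
  n_missing <- 0L
  if (!is.null(subset)) {
    missing <- setdiff(subset, records$query_id)
    n_missing <- length(missing)
    if (n_missing) {
      message(sprintf("%d subset ID(s) with no annotation record counted as unannotated",
                      n_missing))
    }
    records <- records[records$query_id %in% subset, , drop = FALSE]
  }
  annotated <- records[nzchar(records$cog_letters), , drop = FALSE]
  unannotated <- nrow(records) - nrow(annotated) + n_missing
  if (!nrow(annotated)) {
    tab <- data.frame(category = character(0), count = numeric(0),
                      percentage = numeric(0))
  } else {
    letters_list <- strsplit(annotated$cog_letters, "", fixed = TRUE)
    weights <- if (fractional) 1 / lengths(letters_list) else 1
    counts <- tapply(rep(weights, lengths(letters_list)),
                     unlist(letters_list), sum)
    counts <- counts[order(-counts, names(counts))]
    tab <- data.frame(category = names(counts),
                      count = as.numeric(counts),
                      percentage = 100 * as.numeric(counts) / sum(counts))
    rownames(tab) <- NULL
  }
  structure(list(table = tab,
                 total_annotated = nrow(annotated),
                 unannotated = unannotated),
            class = "cog_distribution")
}

#' @export
print.cog_distribution <- function(x, ...) {
  cat(sprintf("<cog_distribution> %d annotated, %d unannotated\n",
              x$total_annotated, x$unannotated))
  if (nrow(x$table)) {
    top <- head(x$table, 3L)
    cat("  top:", paste(sprintf("%s %.2f%%", top$category, top$percentage),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count hypothetical-protein annotations
#'
#' @param descriptions character vector (or named map) of product
#'   descriptions.
#' @return Number of descriptions case-insensitively containing
#'   "hypothetical protein".
#' @export
hypothetical_count <- function(descriptions) {
  if (!length(descriptions)) return(0L)
  sum(grepl("hypothetical protein", descriptions, ignore.case = TRUE))
}

#' Write COG distributions across methods as TSV
#'
#' One row per COG category, one count column per provided distribution
#' (e.g. lr, rf, svm, union).
#'
#' @param distributions named list of `cog_distribution` objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cog_tsv <- function(distributions, path) {
  stopifnot(length(distributions) >= 1L,
            all(vapply(distributions, inherits, TRUE, "cog_distribution")))
  cats <- sort_c(unique(unlist(lapply(distributions,
                                      function(d) d$table$category))))
  out <- data.frame(category = cats)
  for (nm in names(distributions)) {
    tab <- distributions[[nm]]$table
    out[[nm]] <- tab$count[match(cats, tab$category)]
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
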