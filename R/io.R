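#' Read a gene presence/absence matrix in Rtab format
#'
#' The Rtab dialect (as exported by pangenome graph tools) is tab-separated
#' with gene families as rows: the first column holds family IDs and the
#' header row holds genome IDs. Cells must be 0 or 1. The returned object is
#' transposed to the in-memory orientation (genomes as rows) and carries no
#' labels until [attach_labels()] is called.
#'
#' @param path path to an Rtab file.
#' @return An unlabeled [new_pangenome()].
#' @export
read_rtab <- function(path) {
  read_presence_table(path, sep = "\t", coerce_copy_number = FALSE)
}

#' Read a presence/absence matrix in CSV form
#'
#' Same layout as [read_rtab()] but comma-separated. Copy-number values
#' greater than 1 are coerced to presence (1) with a warning, since the
#' selection pipeline is strictly binary.
#'
#' @inheritParams read_rtab
#' @return An unlabeled [new_pangenome()].
#' @export
read_presence_csv <- function(path) {
  read_presence_table(path, sep = ",", coerce_copy_number = TRUE)
}

read_presence_table <- function(path, sep, coerce_copy_number) {
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("presence matrix has no genome columns", call. = FALSE)
  fam <- dt[[1L]]
  if (anyDuplicated(fam)) {
    stop("duplicate family ID(s): ",
         paste(unique(fam[duplicated(fam)]), collapse = ", "), call. = FALSE)
  }
  genomes <- colnames(dt)[-1L]
  if (nrow(dt) == 0L) {
    out <- matrix(integer(0), nrow = length(genomes), ncol = 0L,
                  dimnames = list(genomes, character(0)))
    return(new_pangenome(out))
  }
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))
    stop("non-numeric presence value(s), e.g. for family '",
         fam[((bad[1] - 1) %% nrow(m)) + 1], "'", call. = FALSE)
  }
  if (coerce_copy_number && any(m > 1)) {
    warning(sprintf("%d copy-number value(s) > 1 coerced to presence (1)",
                    sum(m > 1)), call. = FALSE)
    m[m > 1] <- 1
  }
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("non-binary cell '%s' for family '%s', genome '%s'",
                 format(m[bad[1]]), fam[i], genomes[j]), call. = FALSE)
  }
  out <- t(m)
  dimnames(out) <- list(genomes, fam)
  new_pangenome(out)
}

#' Write a pangenome as Rtab
#'
#' Families as rows, genomes as columns, tab-separated; the exact inverse of
#' [read_rtab()].
#'
#' @param pangenome a `pangenome` (labels, if any, are not written; see
#'   [write_labels()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_rtab <- function(pangenome, path) {
  stopifnot(inherits(pangenome, "pangenome"))
  if (ncol(pangenome$presence) == 0L) {
    writeLines(paste(c("Gene", genome_ids(pangenome)), collapse = "\t"), path)
    return(invisible(path))
  }
  m <- t(pangenome$presence)
  df <- data.frame(Gene = colnames(pangenome$presence), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write genome group labels as a two-column TSV
#'
#' @param pangenome a labeled `pangenome`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(pangenome, path) {
  assert_labeled(pangenome)
  utils::write.table(
    data.frame(genome_id = genome_ids(pangenome),
               group = as.character(pangenome$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome label table
#'
#' @param path two-column TSV (genome_id, group), with or without a header.
#' @return A data frame with columns `genome_id` and `group`.
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE,
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 2L) stop("label table needs two columns", call. = FALSE)
  out <- dt[, 1:2]
  colnames(out) <- c("genome_id", "group")
  out
}

#' Attach group labels to a presence/absence matrix
#'
#' Every genome in the matrix must appear exactly once in the label table and
#' the matched genomes must carry exactly two label levels. Label-table rows
#' for genomes absent from the matrix are ignored with a warning.
#'
#' @param pangenome an unlabeled (or labeled) `pangenome`.
#' @param label_table a data frame whose first two columns are genome ID and
#'   group, or a path readable by [read_labels()].
#' @return A labeled `pangenome`.
#' @export
attach_labels <- function(pangenome, label_table) {
  stopifnot(inherits(pangenome, "pangenome"))
  if (is.character(label_table) && length(label_table) == 1L) {
    label_table <- read_labels(label_table)
  }
  ids <- as.character(label_table[[1L]])
  grp <- as.character(label_table[[2L]])
  if (anyDuplicated(ids)) {
    stop("duplicate genome ID(s) in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(genome_ids(pangenome), ids)
  if (length(missing)) {
    stop("label table is missing genome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(ids, genome_ids(pangenome))
  if (length(extra)) {
    warning(sprintf("%d labeled genome(s) absent from the matrix ignored: %s",
                    length(extra), paste(head(extra, 5L), collapse = ", ")),
            call. = FALSE)
  }
  keep <- match(genome_ids(pangenome), ids)
  labels <- grp[keep]
  lev <- unique(labels)
  if (length(lev) != 2L) {
    stop(sprintf("exactly two label levels required among matched genomes, found %d (%s)",
                 length(lev), paste(lev, collapse = ", ")), call. = FALSE)
  }
  new_pangenome(pangenome$presence, factor(labels, levels = sort_c(lev)))
}

#' Parse an eggNOG-mapper annotation table
#'
#' Reads a `.emapper.annotations`-style TSV: comment lines start with `#`
#' (the column-name line, when present, starts with `#query` and is used to
#' locate the query, e-value, COG category and description columns; otherwise
#' the standard positions 1, 3, 7 and 8 are assumed). Records whose e-value
#' exceeds `max_evalue` are excluded — a record at exactly the threshold is
#' retained. A missing COG field (`-` or empty) yields empty `cog_letters`.
#'
#' @param path path to the annotation file.
#' @param max_evalue maximum e-value for a record to be kept (default 6e-5).
#' @return A data frame with columns `query_id`, `evalue`, `cog_letters`,
#'   `description`.
#' @export
read_emapper <- function(path, max_evalue = 6e-5) {
  stopifnot(is.numeric(max_evalue), max_evalue >= 0)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  cols <- c(query = 1L, evalue = 3L, cog = 7L, desc = 8L)
  n_fields <- NA_integer_
  header <- lines[is_comment & startsWith(lines, "#query")]
  if (length(header)) {
    hf <- strsplit(sub("^#", "", header[1L]), "\t", fixed = TRUE)[[1L]]
    find <- function(pats) {
      hit <- which(tolower(hf) %in% pats)
      if (length(hit)) hit[1L] else NA_integer_
    }
    cand <- c(query = find("query"),
              evalue = find(c("evalue", "e-value")),
              cog = find(c("cog_category", "cog category", "cog")),
              desc = find("description"))
    cols[!is.na(cand)] <- cand[!is.na(cand)]
    n_fields <- length(hf)
  }
  data_idx <- which(!is_comment & nzchar(lines))
  if (!length(data_idx)) {
    return(data.frame(query_id = character(0), evalue = numeric(0),
                      cog_letters = character(0), description = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  need <- max(cols)
  lens <- lengths(fields)
  expected <- if (!is.na(n_fields)) n_fields else max(lens[1L], need)
  bad <- which(lens < need | (!is.na(n_fields) & lens != n_fields))
  if (length(bad)) {
    stop(sprintf("malformed annotation row at line %d: %d field(s), expected %d",
                 data_idx[bad[1L]], lens[bad[1L]], expected), call. = FALSE)
  }
  pick <- function(k) vapply(fields, `[[`, "", cols[[k]])
  ev <- suppressWarnings(as.numeric(pick("evalue")))
  if (anyNA(ev)) {
    stop(sprintf("non-numeric e-value at line %d",
                 data_idx[which(is.na(ev))[1L]]), call. = FALSE)
  }
  cog <- pick("cog")
  cog[cog == "-"] <- ""
  out <- data.frame(query_id = pick("query"), evalue = ev,
                    cog_letters = cog, description = pick("desc"),
                    stringsAsFactors = FALSE)
  out <- out[out$evalue <= max_evalue, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper used to supply sequences to [deduplicate()]; requires the
#' Biostrings package.
#'
#' @param path FASTA path.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("the Biostrings package is required to read FASTA", call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}
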