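#' OTU-by-sample count tables
#'
#' A `count_table` is the pivot of every downstream stage of the pipeline: a
#' non-negative integer matrix with one row per OTU and one column per
#' sample. Row names are OTU ids, column names are sample ids; both must be
#' unique, every OTU must be observed at least once somewhere, and column
#' sums are the per-sample read totals.
#'
#' @param counts integer matrix (OTU rows x sample columns) with unique
#'   dimnames.
#' @return An object of class `count_table` (an integer matrix).
#' @examples
#' m <- matrix(c(2L, 1L, 0L, 0L, 1L, 3L), nrow = 3,
#'             dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
#' ct <- count_table(m)
#' sample_totals(ct)
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  # R drops zero-length dimnames to NULL, so an empty table (a legitimate
  # outcome of fraction filtering) cannot carry row names
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("count_table requires OTU row names and sample column names")
  storage.mode(counts) <- "integer"
  obj <- structure(counts, class = c("count_table", "matrix", "array"))
  validate_count_table(obj)
  obj
}

#' @rdname count_table
#' @param x object to validate / test.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.integer(x))
    stop("counts must be an integer matrix")
  if (anyNA(x)) stop("counts contain NA")
  if (any(x < 0L)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(x))) stop("duplicate OTU ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (nrow(x) > 0 && any(rowSums(x) == 0L))
    stop("every OTU row must have at least one positive entry: ",
         paste(utils::head(rownames(x)[rowSums(x) == 0L], 5), collapse = ", "))
  invisible(x)
}

#' @rdname count_table
#' @export
is_count_table <- function(x) inherits(x, "count_table")

#' @rdname count_table
#' @export
sample_totals <- function(x) colSums(unclass(x))

#' @rdname count_table
#' @export
otu_ids <- function(x) rownames(x)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x)

#' Read an OTU count table
#'
#' Two dialects are supported. `plain-tsv`: a header line `otu_id<TAB>s1...`
#' followed by one row per OTU. `mothur-shared`: the mothur "shared" layout
#' (columns `label`, `Group`, `numOtus`, then one column per OTU; one row
#' per sample), which is transposed into the canonical OTU-row orientation
#' at the boundary so all downstream math sees one shape.
#'
#' @param path file path.
#' @param dialect `"plain-tsv"` or `"mothur-shared"`.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, dialect = c("plain-tsv", "mothur-shared")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("count table file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop("ragged row at line ", which(nf != nf[1])[1], " in ", path)
  header <- fields[[1]]
  body <- fields[-1]

  if (dialect == "plain-tsv") {
    sample_names <- header[-1]
    otus <- vapply(body, `[[`, "", 1)
    mat <- matrix(0L, nrow = length(body), ncol = length(sample_names),
                  dimnames = list(otus, sample_names))
    for (i in seq_along(body)) {
      vals <- body[[i]][-1]
      suppressWarnings(num <- as.numeric(vals))
      bad <- is.na(num) | num < 0 | num != floor(num)
      if (any(bad)) stop("non-integer or negative count at line ", i + 1L, ": ", vals[which(bad)[1]])
      mat[i, ] <- as.integer(num)
    }
  } else {
    if (!identical(tolower(header[1:3]), c("label", "group", "numotus")))
      stop("not a mothur shared header: ", paste(header[1:3], collapse = " "))
    otus <- header[-(1:3)]
    groups <- vapply(body, `[[`, "", 2)
    mat <- matrix(0L, nrow = length(otus), ncol = length(groups),
                  dimnames = list(otus, groups))
    for (j in seq_along(body)) {
      n_otus <- suppressWarnings(as.integer(body[[j]][3]))
      if (is.na(n_otus) || n_otus != length(otus))
        stop("numOtus mismatch at line ", j + 1L)
      vals <- body[[j]][-(1:3)]
      suppressWarnings(num <- as.numeric(vals))
      bad <- is.na(num) | num < 0 | num != floor(num)
      if (any(bad)) stop("non-integer or negative count at line ", j + 1L, ": ", vals[which(bad)[1]])
      mat[, j] <- as.integer(num)
    }
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate OTU ids in ", path)
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids in ", path)
  # files may legitimately carry all-zero OTU columns (mothur writes the
  # joint OTU list); drop them so the invariant holds
  mat <- mat[rowSums(mat) > 0L, , drop = FALSE]
  count_table(mat)
}

#' Write an OTU count table
#'
#' Round-trips bit-exactly with [read_count_table()] on both dialects.
#'
#' @param x a [count_table()].
#' @param path output file path.
#' @param dialect `"plain-tsv"` or `"mothur-shared"`.
#' @param label mothur distance label written in the `label` column.
#' @export
write_count_table <- function(x, path, dialect = c("plain-tsv", "mothur-shared"),
                              label = "0.03") {
  dialect <- match.arg(dialect)
  validate_count_table(x)
  m <- unclass(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "plain-tsv") {
    writeLines(paste(c("otu_id", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
  } else {
    writeLines(paste(c("label", "Group", "numOtus", rownames(m)), collapse = "\t"), con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(c(label, colnames(m)[j], nrow(m), m[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with columns `otu_id`, `lineage` (semicolon-ranked string) and
#' `percent_identity` (identity to the nearest reference relative, 0-100).
#' OTUs whose identity to their closest reference relative falls below the
#' phylum-assignment threshold are treated as "unclassified" at the phylum
#' rank (see [collapse_to_phylum()]).
#'
#' @param path TSV file path.
#' @return data.frame with columns otu_id, lineage, percent_identity.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("otu_id", "lineage", "percent_identity")
  if (!all(need %in% names(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy table")
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    stop("percent_identity must lie in [0, 100]")
  df[, need]
}

#' Phylum of each OTU under the conservative identity threshold
#'
#' The phylum is the second-rank entry of the lineage; OTUs with identity
#' to their closest reference relative below `threshold` (default 85%) are
#' pooled as "unclassified".
#'
#' @param tax taxonomy data.frame from [read_taxonomy()].
#' @param threshold percent-identity threshold below which an OTU is
#'   unclassified at the phylum rank.
#' @return named character vector, otu_id -> phylum.
#' @export
phylum_of <- function(tax, threshold = 85) {
  ranks <- strsplit(tax$lineage, ";", fixed = TRUE)
  phyla <- vapply(ranks, function(r) if (length(r) >= 2) trimws(r[2]) else "unclassified", "")
  phyla[tax$percent_identity < threshold] <- "unclassified"
  stats::setNames(phyla, tax$otu_id)
}

#' Collapse an OTU table to phylum level
#'
#' Sums OTU rows by phylum; reads are never created or destroyed, so column
#' totals are preserved exactly. OTUs below the identity threshold are pooled
#' into a single "unclassified" row.
#'
#' @inheritParams phylum_of
#' @param x a [count_table()].
#' @return a [count_table()] keyed by phylum.
#' @export
collapse_to_phylum <- function(x, tax, threshold = 85) {
  validate_count_table(x)
  ph <- phylum_of(tax, threshold)
  missing <- setdiff(rownames(x), names(ph))
  if (length(missing))
    stop("OTUs missing from taxonomy table: ",
         paste(utils::head(missing, 10), collapse = ", "))
  groups <- ph[rownames(x)]
  out <- rowsum(unclass(x), group = groups)
  count_table(out[order(rownames(out)), , drop = FALSE])
}

#' Subset samples of a count table
#'
#' Drops OTU rows that become all-zero in the subset.
#'
#' @param x a [count_table()].
#' @param samples character vector of sample ids to keep, in order.
#' @export
subset_samples <- function(x, samples) {
  validate_count_table(x)
  missing <- setdiff(samples, colnames(x))
  if (length(missing)) stop("unknown sample ids: ", paste(missing, collapse = ", "))
  m <- unclass(x)[, samples, drop = FALSE]
  count_table(m[rowSums(m) > 0L, , drop = FALSE])
}

#' Merge count tables
#'
#' Column set is the union of the inputs' samples (collisions are an error);
#' counts for OTU ids shared across tables are aligned on id, so the grand
#' total is the sum of the inputs' totals.
#'
#' @param tables list of [count_table()] objects.
#' @return a merged [count_table()].
#' @export
merge_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  lapply(tables, validate_count_table)
  all_samples <- unlist(lapply(tables, colnames))
  if (anyDuplicated(all_samples))
    stop("sample id collision on merge: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  all_otus <- unique(unlist(lapply(tables, rownames)))
  out <- matrix(0L, nrow = length(all_otus), ncol = length(all_samples),
                dimnames = list(all_otus, all_samples))
  for (tb in tables) out[rownames(tb), colnames(tb)] <- unclass(tb)
  count_table(out)
}

#' Pool all samples of a table into one total column
#'
#' @param x a [count_table()].
#' @param name name for the pooled column.
#' @export
pool_samples <- function(x, name = "total") {
  validate_count_table(x)
  m <- matrix(as.integer(rowSums(unclass(x))), ncol = 1,
              dimnames = list(rownames(x), name))
  count_table(m)
}

#' Read representative sequences
#'
#' FASTA of one representative sequence per OTU id.
#'
#' @param path FASTA file.
#' @return named character vector of DNA sequences.
#' @export
read_rep_seqs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  if (anyDuplicated(names(out))) stop("duplicate sequence ids in ", path)
  if (any(nchar(out) == 0)) stop("empty sequence in ", path)
  out
}

#' Write representative sequences
#' @param seqs named character vector of DNA sequences.
#' @param path output FASTA path.
#' @export
write_rep_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples, %d reads\n",
              nrow(x), ncol(x), sum(x)))
  cat("sample totals:", paste(sprintf("%s=%d", colnames(x), sample_totals(x)),
                              collapse = ", "), "\n")
  invisible(x)
}
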