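#' Quality-filter configuration for raw amplicon reads
#'
#' Five filters, applied in a fixed order so that per-filter attrition
#' counts are deterministic: (1) mean Phred quality of the full read below
#' `min_mean_quality`; (2) the forward primer is not an exact prefix of the
#' read; (3) any ambiguous base (N); (4) a homopolymer run longer than
#' `max_homopolymer`; (5) read shorter than `min_length_bp`. The length
#' check is applied to the primer-trimmed sequence by default
#' (`length_after_trim = TRUE`); mean quality is always computed on the
#' full read.
#'
#' @param min_mean_quality minimum arithmetic-mean Phred score (default 25).
#' @param forward_primer exact 5' primer sequence; `""` disables the primer
#'   filter and no trimming occurs. Default is the 27F bacterial primer.
#' @param max_homopolymer longest allowed run of one base (default 8).
#' @param min_length_bp minimum length in bp (default 80).
#' @param allow_ambiguous if `TRUE`, reads containing N are kept.
#' @param length_after_trim measure length after primer removal (default)
#'   or on the raw read.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_mean_quality = 25,
                      forward_primer = "AGAGTTTGATCCTGGCTCAG",
                      max_homopolymer = 8L,
                      min_length_bp = 80L,
                      allow_ambiguous = FALSE,
                      length_after_trim = TRUE) {
  stopifnot(min_mean_quality > 0, max_homopolymer >= 1, min_length_bp >= 1)
  structure(list(min_mean_quality = min_mean_quality,
                 forward_primer = toupper(forward_primer),
                 max_homopolymer = as.integer(max_homopolymer),
                 min_length_bp = as.integer(min_length_bp),
                 allow_ambiguous = isTRUE(allow_ambiguous),
                 length_after_trim = isTRUE(length_after_trim)),
            class = "qc_config")
}

qc_filter_names <- c("mean_quality", "primer", "ambiguous", "homopolymer", "length")

longest_homopolymer <- function(seq) {
  if (nchar(seq) == 0) return(0L)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' Apply the five quality filters to one read
#'
#' @param sequence DNA string over A,C,G,T,N.
#' @param qualities integer vector of Phred scores, one per base.
#' @param config a [qc_config()].
#' @return list with `pass` (logical), `failed` (name of the FIRST violated
#'   filter, or `NA`), and `trimmed` (primer-trimmed sequence when the read
#'   passes).
#' @export
filter_read <- function(sequence, qualities, config = qc_config()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != length(qualities))
    stop("quality/sequence length mismatch (", nchar(sequence), " vs ",
         length(qualities), ")")
  fail <- function(which) list(pass = FALSE, failed = which, trimmed = NA_character_)

  if (nchar(sequence) == 0) return(fail("length"))
  if (mean(qualities) < config$min_mean_quality) return(fail("mean_quality"))

  primer <- config$forward_primer
  has_primer <- nzchar(primer)
  if (has_primer && !startsWith(sequence, primer)) return(fail("primer"))
  trimmed <- if (has_primer) substr(sequence, nchar(primer) + 1L, nchar(sequence)) else sequence

  if (!config$allow_ambiguous && grepl("N", sequence, fixed = TRUE))
    return(fail("ambiguous"))
  if (longest_homopolymer(sequence) > config$max_homopolymer)
    return(fail("homopolymer"))
  measured <- if (config$length_after_trim) trimmed else sequence
  if (nchar(measured) < config$min_length_bp) return(fail("length"))
  list(pass = TRUE, failed = NA_character_, trimmed = trimmed)
}

#' Filter a batch of reads and report per-filter attrition
#'
#' Every input read is attributed either to the retained set or to exactly
#' one failing filter (the first violated one in the fixed order), so the
#' counts always conserve the input total. Retained reads are emitted in
#' input order with the primer trimmed.
#'
#' @param reads list of reads, each a list with `id`, `sequence`,
#'   `qualities` (as produced by [read_fastq()]).
#' @param config a [qc_config()].
#' @return list with `report` (a `qc_report`: total_in, passed,
#'   failed_by_filter, retention_fraction) and `retained` (list of reads,
#'   primer-trimmed, qualities trimmed to match).
#' @export
filter_batch <- function(reads, config = qc_config()) {
  failed <- stats::setNames(integer(length(qc_filter_names)), qc_filter_names)
  retained <- vector("list", length(reads))
  n_keep <- 0L
  primer_len <- nchar(config$forward_primer)
  for (rd in reads) {
    res <- filter_read(rd$sequence, rd$qualities, config)
    if (res$pass) {
      n_keep <- n_keep + 1L
      qual <- rd$qualities
      if (primer_len > 0) qual <- qual[-seq_len(primer_len)]
      retained[[n_keep]] <- list(id = rd$id, sequence = res$trimmed, qualities = qual)
    } else {
      failed[res$failed] <- failed[res$failed] + 1L
    }
  }
  retained <- retained[seq_len(n_keep)]
  total <- length(reads)
  report <- structure(list(
    total_in = total,
    passed = n_keep,
    failed_by_filter = as.list(failed),
    retention_fraction = if (total == 0) 1 else n_keep / total
  ), class = "qc_report")
  list(report = report, retained = retained)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d reads retained (%.1f%%)\n",
              x$passed, x$total_in, 100 * x$retention_fraction))
  f <- unlist(x$failed_by_filter)
  for (nm in names(f)) if (f[[nm]] > 0) cat(sprintf("  failed %s: %d\n", nm, f[[nm]]))
  invisible(x)
}

#' Read a FASTQ file into the pipeline's read representation
#'
#' Sanger/Phred+33 encoding.
#'
#' @param path FASTQ file.
#' @return list of reads: each `list(id, sequence, qualities)`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns here
  qs <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  quals <- as(Biostrings::quality(qs), "IntegerList")
  ids <- sub("\\s.*$", "", names(qs))
  lapply(seq_along(qs), function(i)
    list(id = ids[i], sequence = as.character(qs[[i]]), qualities = as.integer(quals[[i]])))
}

#' Write reads to FASTQ (Phred+33)
#' @param reads list of reads (`id`, `sequence`, `qualities`).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rd in reads) {
    writeLines(c(paste0("@", rd$id), rd$sequence, "+",
                 intToUtf8(rd$qualities + 33L)), con)
  }
  invisible(path)
}

#' Write retained reads to FASTA
#' @param reads list of reads.
#' @param path output path.
#' @export
write_reads_fasta <- function(reads, path) {
  seqs <- stats::setNames(vapply(reads, `[[`, "", "sequence"),
                          vapply(reads, `[[`, "", "id"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("total_in", "passed", paste0("failed_", names(report$failed_by_filter)),
               "retention_fraction"),
    value = c(report$total_in, report$passed, unlist(report$failed_by_filter),
              report$retention_fraction))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
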