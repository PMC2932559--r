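#' Count cutoff equivalent to a relative-abundance rarity threshold
#'
#' The largest integer count not exceeding `proportion` of the sample's
#' read total, i.e. `floor(proportion * total_reads)`. This is how a
#' percentage-abundance rarity definition (e.g. 0.004%) converts to a
#' per-sample count cutoff when sample depths differ.
#'
#' @param total_reads per-sample read total (>= 1).
#' @param proportion rarity threshold as a proportion in (0, 1), e.g.
#'   0.004% = 0.00004.
#' @return integer count cutoff (possibly 0, in which case the rare set
#'   under `count <= cutoff` is empty).
#' @export
count_cutoff_for_proportion <- function(total_reads, proportion) {
  stopifnot(total_reads >= 1, proportion > 0, proportion < 1)
  as.integer(floor(proportion * total_reads))
}

#' Partition one sample's OTUs into rare and abundant
#'
#' Count mode: rare OTUs have `0 < count <= threshold` (rare side) or
#' abundant OTUs have `count > threshold` (abundant side); proportion mode
#' converts the threshold to a count cutoff via
#' [count_cutoff_for_proportion()] first (rare side) or classifies OTUs
#' with relative abundance strictly above the threshold as abundant
#' (abundant side). With thresholds `n <= t` and `n > t` the two sides
#' partition the sample's observed OTUs.
#'
#' @param x a [count_table()].
#' @param sample sample id.
#' @param threshold numeric cutoff: a count for `mode = "count"`, a
#'   proportion in (0, 1) for `mode = "proportion"`.
#' @param mode `"count"` or `"proportion"`.
#' @param side `"rare"` (`<=` threshold) or `"abundant"` (`>` threshold).
#' @return list with `selected` (OTU ids on the requested side),
#'   `complement` (the other observed OTUs), and the effective count
#'   `cutoff`.
#' @export
partition_abundance <- function(x, sample, threshold,
                                mode = c("count", "proportion"),
                                side = c("rare", "abundant")) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  validate_count_table(x)
  if (!sample %in% colnames(x)) stop("unknown sample id: ", sample)
  counts <- unclass(x)[, sample]
  observed <- counts > 0L
  total <- sum(counts)
  if (mode == "proportion") {
    if (side == "rare") {
      cutoff <- count_cutoff_for_proportion(total, threshold)
    } else {
      # abundant at relative abundance strictly > threshold
      cutoff <- as.integer(floor(threshold * total))
    }
  } else {
    cutoff <- as.integer(threshold)
  }
  sel <- if (side == "rare") observed & counts <= cutoff
         else observed & counts > cutoff
  list(selected = rownames(x)[sel],
       complement = rownames(x)[observed & !sel],
       cutoff = cutoff)
}

#' Restrict a count table to the rare (or abundant) fraction of each sample
#'
#' Applies [partition_abundance()] per sample and zeroes the entries on the
#' other side, so downstream index and Venn machinery can run unchanged on
#' the selected fraction. OTU rows that become all-zero are dropped.
#'
#' @inheritParams partition_abundance
#' @export
fraction_table <- function(x, threshold, mode = c("count", "proportion"),
                           side = c("rare", "abundant")) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  validate_count_table(x)
  m <- unclass(x)
  out <- m
  for (s in colnames(m)) {
    keep <- partition_abundance(x, s, threshold, mode, side)$selected
    out[!(rownames(m) %in% keep), s] <- 0L
  }
  out <- out[rowSums(out) > 0L, , drop = FALSE]
  count_table(out)
}

# alignment columns (matches + mismatches + gap positions) from the cheap
# accessors; equivalent to the width of the gapped aligned pattern
alignment_columns <- function(aln) {
  ind <- Biostrings::nindel(aln)
  as.integer(Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
             Biostrings::insertion(ind)[, "WidthSum"] +
             Biostrings::deletion(ind)[, "WidthSum"])
}

# the base-only ACGT substitution matrix is dramatically faster in
# Biostrings; fall back to the full IUPAC matrix only when a sequence
# carries ambiguity codes
sw_substitution_matrix <- function(seqs) {
  base_only <- !any(grepl("[^ACGT]", toupper(seqs)))
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = base_only)
}

#' Percent identity of the best local alignment of two sequences
#'
#' Smith-Waterman local alignment with match +1, mismatch -1, and an
#' affine gap penalty where a length-L gap costs 1 + L (the first gap
#' column costs 2, each extension 1 more). Identity is
#' matches / alignment columns x 100, with alignment columns counting
#' matches, mismatches and gap positions of the locally aligned region.
#'
#' @param seq1,seq2 non-empty DNA strings.
#' @return list with `percent_identity`, `alignment_length`, `matches`,
#'   `score`.
#' @export
percent_identity <- function(seq1, seq2) {
  stopifnot(nzchar(seq1), nzchar(seq2))
  mat <- sw_substitution_matrix(c(seq1, seq2))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq1), Biostrings::DNAString(seq2),
    type = "local", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1)
  len <- alignment_columns(aln)
  matches <- Biostrings::nmatch(aln)
  list(percent_identity = if (len > 0) 100 * matches / len else 0,
       alignment_length = len,
       matches = matches,
       score = Biostrings::score(aln))
}

# all local alignments of one query against a set of subjects in a single
# vectorised call
identity_hits <- function(query, subjects) {
  mat <- sw_substitution_matrix(c(query, unname(subjects)))
  subj <- Biostrings::DNAStringSet(subjects)
  aln <- Biostrings::pairwiseAlignment(
    subj, Biostrings::DNAString(query),
    type = "local", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1)
  lens <- alignment_columns(aln)
  matches <- Biostrings::nmatch(aln)
  data.frame(subject_id = names(subjects),
             percent_identity = ifelse(lens > 0, 100 * matches / lens, 0),
             alignment_length = as.integer(lens),
             matches = as.integer(matches),
             score = Biostrings::score(aln),
             stringsAsFactors = FALSE)
}

# best hit of one query against a set of subjects, ranked by alignment
# score (as BLAST ranks hits; a short perfect match must not outrank a
# long near-identical alignment), with ties broken by higher identity,
# then longer alignment, then lexicographic subject id
best_hit <- function(query, subjects) {
  if (length(subjects) == 0) return(NULL)
  h <- identity_hits(query, subjects)
  ord <- order(-h$score, -h$percent_identity, -h$alignment_length,
               h$subject_id)
  as.list(h[ord[1], ])
}

#' Sub-classify rare OTUs by novelty and uniqueness (NUNN / UNN / UN)
#'
#' Two-stage decision per rare OTU: (1) if its best hit against the
#' abundant representative set has identity strictly above
#' `min_identity` AND alignment length at least `min_aln_len`, it is
#' non-unique non-novel (NUNN) — a rare member with a close relative
#' among the abundant community; (2) otherwise, if its best identity to a
#' reference database is strictly above `min_identity`, it is unique but
#' non-novel (UNN); (3) otherwise it is unique and novel (UN). Reference
#' evidence can be a FASTA set (aligned here) or a precomputed named
#' vector of best identities from an external classifier.
#'
#' @param rare_seqs named character vector: rare OTU id -> representative
#'   sequence.
#' @param abundant_seqs named character vector for the abundant set.
#' @param reference either a named character vector of reference sequences
#'   or a named numeric vector `otu_id -> best percent identity`.
#' @param weights optional named numeric vector of read counts per rare
#'   OTU (for read-weighted proportions); default 1 per OTU.
#' @param min_identity identity gate, default 85 (strictly greater).
#' @param min_aln_len alignment-length gate for the abundant comparison,
#'   default 100 bp.
#' @return list with `labels` (data.frame: otu_id, label, identity and
#'   length of the best abundant hit, best reference identity),
#'   `proportions_otu` and `proportions_reads` (named vectors over NUNN,
#'   UNN, UN summing to 100).
#' @export
classify_rare <- function(rare_seqs, abundant_seqs, reference,
                          weights = NULL,
                          min_identity = 85, min_aln_len = 100) {
  if (length(intersect(names(rare_seqs), names(abundant_seqs))))
    stop("rare and abundant sets must be disjoint")
  if (any(!nzchar(rare_seqs)))
    stop("missing representative sequence for rare OTUs: ",
         paste(names(rare_seqs)[!nzchar(rare_seqs)], collapse = ", "))
  ref_is_map <- is.numeric(reference)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(rare_seqs)), names(rare_seqs))

  rows <- vector("list", length(rare_seqs))
  for (i in seq_along(rare_seqs)) {
    id <- names(rare_seqs)[i]
    ab <- best_hit(rare_seqs[[i]], abundant_seqs)
    if (!is.null(ab) && ab$percent_identity > min_identity &&
        ab$alignment_length >= min_aln_len) {
      label <- "NUNN"; ref_id <- NA_real_
    } else {
      ref_id <- if (ref_is_map) {
        if (id %in% names(reference)) unname(reference[[id]]) else 0
      } else {
        # when aligning against a reference FASTA the identity is only
        # meaningful over a substantial alignment; short chance matches
        # between unrelated sequences are near-100% identical
        rh <- best_hit(rare_seqs[[i]], reference)
        if (is.null(rh) || rh$alignment_length < min_aln_len) 0
        else rh$percent_identity
      }
      label <- if (ref_id > min_identity) "UNN" else "UN"
    }
    rows[[i]] <- data.frame(
      otu_id = id, label = label,
      abundant_identity = if (is.null(ab)) NA_real_ else ab$percent_identity,
      abundant_aln_len = if (is.null(ab)) NA_integer_ else ab$alignment_length,
      abundant_subject = if (is.null(ab)) NA_character_ else ab$subject_id,
      reference_identity = ref_id,
      weight = unname(weights[id]),
      stringsAsFactors = FALSE)
  }
  labels <- do.call(rbind, rows)
  cats <- c("NUNN", "UNN", "UN")
  prop <- function(w) {
    tot <- sum(w)
    stats::setNames(vapply(cats, function(cl)
      100 * sum(w[labels$label == cl]) / tot, 0), cats)
  }
  list(labels = labels,
       proportions_otu = prop(rep(1, nrow(labels))),
       proportions_reads = prop(labels$weight))
}
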