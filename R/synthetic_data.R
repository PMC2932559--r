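#' Specification of a synthetic replicate-community experiment
#'
#' Describes a metacommunity with a small shared abundant core and a
#' large, partially unshared rare tail, sampled by replicate amplicon
#' surveys. Defaults are the conditions the pipeline's validation studies
#' use; the `"paper"` preset matches the scale of a deep four-replicate
#' pyrosequencing survey (richness ~45,000, ~75,000 reads per replicate),
#' the `"small"` preset is the reduced scale used by the test-suite
#' recovery studies.
#'
#' @param S total metacommunity richness.
#' @param model abundance model: `"geommix"` (two-component
#'   exponential-mixture rates, the same family the richness module fits)
#'   or `"lognormal"` (for misspecification checks).
#' @param w,mu1,mu2 mixture weight and component means of the rate
#'   distribution (geommix model).
#' @param sdlog lognormal shape (lognormal model).
#' @param core_fraction fraction of species (the most abundant ones)
#'   forming the shared core present in every replicate.
#' @param rho rare-tail replacement fraction in \[0, 1\]: the probability
#'   that a rare metacommunity species is replaced, in a given replicate,
#'   by an independently drawn replicate-specific species. `rho = 0`
#'   makes all replicates sample one pool; `rho = 1` gives fully
#'   replicate-specific rare tails.
#' @param R number of replicates.
#' @param depth reads per replicate.
#' @param seq_length representative-sequence length in bp.
#' @param nunn_identity,unn_identity planted percent-identity targets for
#'   the NUNN (vs an abundant parent) and UNN (vs a reference parent)
#'   categories.
#' @param p_nunn,p_unn planting probabilities for rare-OTU categories
#'   (remainder is UN).
#' @param preset `"small"` or `"paper"`: overrides S and depth.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(S = 2000, model = c("geommix", "lognormal"),
                           w = 0.7, mu1 = 0.5, mu2 = 50, sdlog = 2,
                           core_fraction = 0.05, rho = 0.8, R = 4,
                           depth = 5000, seq_length = 250,
                           nunn_identity = 95, unn_identity = 95,
                           p_nunn = 0.905, p_unn = 0.05,
                           preset = NULL, seed = 1) {
  model <- match.arg(model)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("small", "paper"))
    if (preset == "paper") { S <- 45000; depth <- 75000 }
    else { S <- 2000; depth <- 5000 }
  }
  stopifnot(rho >= 0, rho <= 1, depth >= 1, S >= 10, R >= 2,
            core_fraction > 0, core_fraction < 1,
            nunn_identity > 0, nunn_identity <= 100,
            unn_identity > 0, unn_identity <= 100,
            p_nunn + p_unn <= 1)
  structure(list(S = as.integer(S), model = model, w = w, mu1 = mu1,
                 mu2 = mu2, sdlog = sdlog, core_fraction = core_fraction,
                 rho = rho, R = as.integer(R), depth = as.integer(depth),
                 seq_length = as.integer(seq_length),
                 nunn_identity = nunn_identity, unn_identity = unn_identity,
                 p_nunn = p_nunn, p_unn = p_unn, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic replicate community with known structure
#'
#' Metacommunity species rates are drawn from the abundance model; the
#' `core_fraction` most abundant species form a core present in every
#' replicate; each remaining (tail) species is, independently per
#' replicate, either kept (probability `1 - rho`) or replaced by a
#' replicate-specific species of the same metacommunity abundance. Reads
#' are then drawn multinomially at `depth` per replicate. Fully seeded
#' and reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [count_table()], replicates named
#'   `q1..qR`) and `truth` (metacommunity abundances, core ids,
#'   per-replicate pools, and the per-species shared/replicate-specific
#'   status).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- withr_seed(spec$seed)
  on.exit(restore_seed(old))
  S <- spec$S
  rates <- if (spec$model == "geommix") {
    comp <- stats::runif(S) < spec$w
    ifelse(comp, stats::rexp(S, 1 / spec$mu1), stats::rexp(S, 1 / spec$mu2))
  } else {
    stats::rlnorm(S, meanlog = 0, sdlog = spec$sdlog)
  }
  ids <- sprintf("sp%05d", seq_len(S))
  names(rates) <- ids
  ord <- order(rates, decreasing = TRUE)
  n_core <- max(1L, ceiling(spec$core_fraction * S))
  core <- ids[ord[seq_len(n_core)]]
  tail_ids <- setdiff(ids, core)

  if (sum(rates[core]) / sum(rates) * spec$depth < 1)
    warning("expected core reads per replicate below 1: depth too small")

  pools <- vector("list", spec$R)
  reps <- paste0("q", seq_len(spec$R))
  names(pools) <- reps
  cols <- list()
  for (r in seq_len(spec$R)) {
    replaced <- stats::runif(length(tail_ids)) < spec$rho
    pool_ids <- c(core, ifelse(replaced,
                               sprintf("%s_%s", reps[r], tail_ids),
                               tail_ids))
    pool_rates <- c(rates[core], unname(rates[tail_ids]))
    names(pool_rates) <- pool_ids
    pools[[r]] <- pool_ids
    draws <- stats::rmultinom(1, spec$depth, pool_rates / sum(pool_rates))[, 1]
    cols[[r]] <- draws[draws > 0]
  }
  all_otus <- sort(unique(unlist(lapply(cols, names))))
  m <- matrix(0L, nrow = length(all_otus), ncol = spec$R,
              dimnames = list(all_otus, reps))
  for (r in seq_len(spec$R)) m[names(cols[[r]]), r] <- as.integer(cols[[r]])
  tb <- count_table(m)

  truth <- list(
    metacommunity = rates / sum(rates),
    core = core,
    tail = tail_ids,
    pools = pools,
    spec = spec)
  list(table = tb, truth = truth)
}

#' Generate representative sequences with planted identity structure
#'
#' Abundant (core) OTUs receive independent random parent sequences.
#' Each rare OTU is planted as NUNN (a mutated copy of a random abundant
#' parent at the NUNN identity target), UNN (a mutated copy of a
#' reference-only parent at the UNN target) or UN (an unrelated random
#' sequence), with the spec's planting probabilities. The reference set
#' contains only the UNN parents, emulating database relatives absent
#' from the abundant community.
#'
#' @param community output of [generate_community()].
#' @param abundant_cutoff count cutoff: OTUs with pooled count above it
#'   are treated as the abundant set, the rest as rare (default 5,
#'   matching a rare biosphere defined at n <= 5 on the pooled table).
#' @return list with `rep_seqs` (named character vector for every OTU in
#'   the table), `reference` (named character vector), `planted`
#'   (data.frame: otu_id, label) and `abundant_ids`.
#' @export
generate_sequences <- function(community, abundant_cutoff = 5) {
  spec <- community$truth$spec
  old <- withr_seed(spec$seed + 1L)
  on.exit(restore_seed(old))
  tb <- community$table
  pooled <- rowSums(unclass(tb))
  abundant_ids <- names(pooled)[pooled > abundant_cutoff]
  rare_ids <- names(pooled)[pooled <= abundant_cutoff]
  L <- spec$seq_length

  ab_seqs <- stats::setNames(random_dna(length(abundant_ids), L), abundant_ids)
  n_ref <- max(10L, ceiling(length(rare_ids) * spec$p_unn))
  ref_seqs <- stats::setNames(random_dna(n_ref, L), sprintf("ref%04d", seq_len(n_ref)))

  u <- stats::runif(length(rare_ids))
  label <- ifelse(u < spec$p_nunn, "NUNN",
                  ifelse(u < spec$p_nunn + spec$p_unn, "UNN", "UN"))
  rare_seqs <- character(length(rare_ids))
  for (i in seq_along(rare_ids)) {
    rare_seqs[i] <- switch(label[i],
      NUNN = mutate_dna(ab_seqs[[sample.int(length(ab_seqs), 1)]],
                        1 - spec$nunn_identity / 100),
      UNN = mutate_dna(ref_seqs[[sample.int(length(ref_seqs), 1)]],
                       1 - spec$unn_identity / 100),
      UN = random_dna(1, L))
  }
  names(rare_seqs) <- rare_ids
  list(rep_seqs = c(ab_seqs, rare_seqs),
       reference = ref_seqs,
       planted = data.frame(otu_id = rare_ids, label = label,
                            stringsAsFactors = FALSE),
       abundant_ids = abundant_ids)
}

#' Generate raw reads with planted quality-filter failures
#'
#' Emits reads in the pipeline's FASTQ representation with each failure
#' mode planted at a controlled rate, so the QC report has a known
#' expectation: low mean quality, a primer mismatch, an ambiguous base,
#' a 9-base homopolymer, or a short read. Rates are per-read
#' probabilities of being assigned that (single) failure mode; the rest
#' pass all filters by construction.
#'
#' @param n number of reads.
#' @param rates named numeric vector over `mean_quality`, `primer`,
#'   `ambiguous`, `homopolymer`, `length` (default all 0); must sum to
#'   <= 1.
#' @param config the [qc_config()] the reads should be tested against.
#' @param read_length length of the post-primer read body.
#' @param seed RNG seed.
#' @return list with `reads` and `planted` (character vector: "pass" or
#'   the planted failure mode, per read).
#' @export
generate_reads_with_quality <- function(n, rates = NULL, config = qc_config(),
                                        read_length = 150, seed = 1) {
  modes <- c("mean_quality", "primer", "ambiguous", "homopolymer", "length")
  r <- stats::setNames(numeric(5), modes)
  if (!is.null(rates)) r[names(rates)] <- rates
  stopifnot(sum(r) <= 1, all(r >= 0))
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  primer <- config$forward_primer
  good_q <- as.integer(config$min_mean_quality) + 10L
  bad_q <- max(as.integer(config$min_mean_quality) - 1L, 1L)
  hp_run <- strrep("A", config$max_homopolymer + 1L)

  # a clean body avoids runs beyond the homopolymer cap by construction
  clean_body <- function(len) {
    b <- random_dna(1, len)
    while (longest_homopolymer(paste0(primer, b)) > config$max_homopolymer)
      b <- random_dna(1, len)
    b
  }

  planted <- sample(c(modes, "pass"), n, replace = TRUE,
                    prob = c(r, 1 - sum(r)))
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    mode <- planted[i]
    body <- clean_body(read_length)
    seqv <- paste0(primer, body)
    qual <- rep(good_q, nchar(seqv))
    if (mode == "mean_quality") {
      qual <- rep(bad_q, nchar(seqv))
    } else if (mode == "primer") {
      bad_primer <- primer
      substr(bad_primer, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                          substr(primer, 1, 1))[1]
      seqv <- paste0(bad_primer, body)
      qual <- rep(good_q, nchar(seqv))
    } else if (mode == "ambiguous") {
      pos <- nchar(primer) + sample.int(read_length, 1)
      substr(seqv, pos, pos) <- "N"
    } else if (mode == "homopolymer") {
      seqv <- paste0(primer, hp_run,
                     clean_body(read_length - nchar(hp_run)))
      qual <- rep(good_q, nchar(seqv))
    } else if (mode == "length") {
      short <- substr(body, 1, config$min_length_bp - 1L)
      seqv <- paste0(primer, short)
      qual <- rep(good_q, nchar(seqv))
    }
    reads[[i]] <- list(id = sprintf("read%06d_%s", i, mode),
                       sequence = seqv, qualities = qual)
  }
  list(reads = reads, planted = planted)
}
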