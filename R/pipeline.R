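#' Pipeline configuration
#'
#' All stage thresholds in one place. Defaults are the study conditions
#' of the analysis: QC at mean quality 25, exact 27F primer, no ambiguous
#' bases, homopolymer cap 8, minimum 80 bp; rarity cutoffs n = 1, n <= 2,
#' n <= 5, n <= 10, proportion 0.004% (rare) and n > 10, 1% (abundant);
#' rare-biosphere classification gates at >85% identity over >= 100 bp;
#' spatial subsample size 28,000 reads; family alpha 0.05 with Bonferroni
#' correction over the 6 pairwise comparisons of 4 replicates (0.0083;
#' phylum-test alpha 0.008).
#'
#' @param qc a [qc_config()].
#' @param rare_cutoffs integer count cutoffs defining rarity.
#' @param rare_proportion proportion cutoff for rarity.
#' @param abundant_cutoff count cutoff above which OTUs are abundant.
#' @param abundant_proportion proportion cutoff for "truly abundant".
#' @param class_cutoff the rare cutoff used for NUNN/UNN/UN
#'   classification (pooled across samples).
#' @param min_identity,min_aln_len classification gates.
#' @param subsample_size spatial-test subsample depth.
#' @param alpha family significance level.
#' @param n_pairwise number of pairwise comparisons for the Bonferroni
#'   correction.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` list with `bonferroni_alpha` computed.
#' @export
pipeline_config <- function(qc = qc_config(),
                            rare_cutoffs = c(1L, 2L, 5L, 10L),
                            rare_proportion = 0.00004,
                            abundant_cutoff = 10L,
                            abundant_proportion = 0.01,
                            class_cutoff = 5L,
                            min_identity = 85, min_aln_len = 100,
                            subsample_size = 28000L,
                            alpha = 0.05, n_pairwise = 6L,
                            seed = 1L) {
  structure(list(qc = qc, rare_cutoffs = as.integer(rare_cutoffs),
                 rare_proportion = rare_proportion,
                 abundant_cutoff = as.integer(abundant_cutoff),
                 abundant_proportion = abundant_proportion,
                 class_cutoff = as.integer(class_cutoff),
                 min_identity = min_identity, min_aln_len = min_aln_len,
                 subsample_size = as.integer(subsample_size),
                 alpha = alpha, n_pairwise = as.integer(n_pairwise),
                 bonferroni_alpha = alpha / n_pairwise,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full beta-diversity analysis on an OTU table
#'
#' Orchestrates the stages on a jointly OTU-labelled count table:
#' pairwise similarity indices for the total community and for every rare
#' and abundant fraction; shared-OTU (Venn) accounting (OTU- and
#' read-weighted); optional NUNN/UNN/UN classification when
#' representative and reference sequences are supplied; the parametric
#' richness fit and shared-singleton null prediction per sample; the
#' observed-vs-predicted singleton comparison; and (when some sample is
#' deep enough) the subsampling spatial-separation test. All randomness
#' derives from `config$seed`, so a rerun with the same inputs and config
#' reproduces every number exactly.
#'
#' @param table a [count_table()] with >= 2 samples.
#' @param config a [pipeline_config()].
#' @param rep_seqs,reference optional named character vectors enabling
#'   the rare-biosphere classification stage.
#' @param subsample_size spatial-test depth; defaults to the config
#'   value, reduced automatically to 1/3 of the deepest sample when that
#'   is smaller.
#' @return a `pipeline_result` list with elements `indices`, `venn_otus`,
#'   `venn_clones`, `fractions`, `classification` (or NULL), `richness`,
#'   `singleton_comparison`, `spatial`, `config`.
#' @export
run_pipeline <- function(table, config = pipeline_config(),
                         rep_seqs = NULL, reference = NULL,
                         subsample_size = NULL) {
  validate_count_table(table)
  smp <- sample_ids(table)
  stopifnot(length(smp) >= 2)

  idx <- lapply(stats::setNames(beta_index_names, beta_index_names),
                function(ix) pairwise_matrix(table, ix))
  indices <- data.frame(
    fraction = "total",
    index = beta_index_names,
    mean = vapply(idx, `[[`, 0, "mean"),
    sd = vapply(idx, `[[`, 0, "sd"), row.names = NULL)

  fractions <- list(total = table)
  for (ct in config$rare_cutoffs)
    fractions[[paste0("rare_n", ct)]] <- try(fraction_table(table, ct, "count", "rare"),
                                             silent = TRUE)
  fractions[[paste0("rare_p", config$rare_proportion)]] <-
    try(fraction_table(table, config$rare_proportion, "proportion", "rare"), silent = TRUE)
  fractions[[paste0("abundant_n", config$abundant_cutoff)]] <-
    try(fraction_table(table, config$abundant_cutoff, "count", "abundant"), silent = TRUE)
  fractions[[paste0("abundant_p", config$abundant_proportion)]] <-
    try(fraction_table(table, config$abundant_proportion, "proportion", "abundant"),
        silent = TRUE)
  fractions <- Filter(function(f) !inherits(f, "try-error") && nrow(f) > 0, fractions)

  for (nm in setdiff(names(fractions), "total")) {
    fr <- fractions[[nm]]
    if (ncol(fr) < 2) next
    rows <- lapply(beta_index_names, function(ix) {
      pm <- try(pairwise_matrix(fr, ix), silent = TRUE)
      if (inherits(pm, "try-error")) return(NULL)
      data.frame(fraction = nm, index = ix, mean = pm$mean, sd = pm$sd)
    })
    indices <- rbind(indices, do.call(rbind, rows))
  }

  venn_otus <- lapply(fractions, function(f) venn_summary(f, weight = "otus"))
  venn_clones <- lapply(fractions, function(f) venn_summary(f, weight = "clones"))

  classification <- NULL
  if (!is.null(rep_seqs) && !is.null(reference)) {
    pooled <- rowSums(unclass(table))
    rare_ids <- names(pooled)[pooled <= config$class_cutoff]
    abundant_ids <- names(pooled)[pooled > config$class_cutoff]
    missing <- setdiff(rare_ids, names(rep_seqs))
    if (length(missing))
      stop("missing representative sequences for rare OTUs: ",
           paste(utils::head(missing, 10), collapse = ", "))
    classification <- classify_rare(
      rep_seqs[rare_ids], rep_seqs[intersect(abundant_ids, names(rep_seqs))],
      reference, weights = pooled[rare_ids],
      min_identity = config$min_identity, min_aln_len = config$min_aln_len)
  }

  richness <- lapply(stats::setNames(smp, smp), function(s) {
    fit <- try(fit_mixed_poisson(frequency_counts(table, s)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    pool <- expected_singleton_pool(fit)
    pred <- predict_shared(max(round(pool), 1), max(fit$f1_observed, 1),
                           R = length(smp))
    list(fit = fit, pool = pool, prediction = pred)
  })
  richness <- Filter(Negate(is.null), richness)

  singleton_comparison <- NULL
  if (length(richness) >= 2) {
    singles <- fraction_table(table, 1L, "count", "rare")
    obs_venn <- venn_summary(singles)
    per <- obs_venn$per_subset
    observed <- list(unshared = per$pct[per$k == 1],
                     shared_2 = per$pct[per$k == 2])
    predicted <- list(
      unshared = vapply(richness, function(z) z$prediction$percentages[["unshared"]], 0),
      shared_2 = vapply(richness, function(z) z$prediction$percentages[["shared_2"]], 0))
    if (length(smp) >= 3) {
      observed$shared_3 <- per$pct[per$k == 3]
      predicted$shared_3 <- vapply(richness, function(z)
        z$prediction$percentages[["shared_3"]], 0)
    }
    singleton_comparison <- suppressWarnings(
      compare_observed_predicted(observed, predicted))
  }

  spatial <- NULL
  totals <- sample_totals(table)
  if (length(smp) == 4) {
    size <- subsample_size
    if (is.null(size)) size <- min(config$subsample_size, floor(max(totals) / 3))
    deepest <- names(which.max(totals))
    others <- setdiff(smp, deepest)
    if (max(totals) >= 3 * size && all(totals[others] >= size))
      spatial <- spatial_separation_test(table, deepest, others, size,
                                         seed = config$seed)
  }

  structure(list(indices = indices, venn_otus = venn_otus,
                 venn_clones = venn_clones, fractions = names(fractions),
                 classification = classification, richness = richness,
                 singleton_comparison = singleton_comparison,
                 spatial = spatial, config = config),
            class = "pipeline_result")
}

#' Write the main pipeline tables to a directory
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if absent).
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$indices, file.path(dir, "similarity_indices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  venn <- lapply(result$venn_otus, function(v)
    list(occupancy = v$occupancy, k_shared = v$k_shared))
  jsonlite::write_json(venn, file.path(dir, "venn_otus.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$classification)) {
    utils::write.table(result$classification$labels,
                       file.path(dir, "rare_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(otu = as.list(result$classification$proportions_otu),
                              reads = as.list(result$classification$proportions_reads)),
                         file.path(dir, "rare_proportions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(result$singleton_comparison))
    utils::write.table(result$singleton_comparison,
                       file.path(dir, "singleton_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$spatial))
    utils::write.table(result$spatial$tests, file.path(dir, "spatial_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
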