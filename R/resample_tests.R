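#' Subsample reads from one sample without replacement
#'
#' Treats the sample's reads as exchangeable tokens labelled by OTU and
#' draws `size` of them without replacement (a multivariate hypergeometric
#' draw), preserving OTU labels. Repeated calls with different seeds give
#' independent subsamples of the same source pool.
#'
#' @param x a [count_table()].
#' @param sample sample id.
#' @param size number of reads to draw (<= the sample's read total).
#' @param seed RNG seed.
#' @param name name of the output column.
#' @return a one-column [count_table()] whose column sums to `size`.
#' @export
subsample_reads <- function(x, sample, size, seed = 1,
                            name = paste0(sample, "_sub")) {
  validate_count_table(x)
  if (!sample %in% colnames(x)) stop("unknown sample id: ", sample)
  counts <- unclass(x)[, sample]
  counts <- counts[counts > 0L]
  total <- sum(counts)
  if (size > total) stop("size (", size, ") exceeds sample total (", total, ")")
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  tokens <- sample.int(total, size)  # positions among the expanded reads
  breaks <- c(0L, cumsum(counts))
  drawn <- tabulate(findInterval(tokens, breaks, left.open = TRUE),
                    nbins = length(counts))
  keep <- drawn > 0L
  m <- matrix(as.integer(drawn[keep]), ncol = 1,
              dimnames = list(names(counts)[keep], name))
  count_table(m)
}

#' Disjoint subsamples partitioning reads of one sample
#'
#' Draws `k * size` reads without replacement from the sample and splits
#' them into `k` disjoint subsamples of `size` reads each. Because the
#' reads of a sample are exchangeable tokens, disjoint subsamples are
#' distributed as independent draws from the underlying community.
#'
#' @inheritParams subsample_reads
#' @param k number of disjoint subsamples.
#' @param names column names for the subsamples.
#' @return list of `k` one-column [count_table()]s.
#' @export
disjoint_subsamples <- function(x, sample, size, k = 3, seed = 1,
                                names = paste0(sample, "_sub", seq_len(k))) {
  validate_count_table(x)
  if (!sample %in% colnames(x)) stop("unknown sample id: ", sample)
  counts <- unclass(x)[, sample]
  counts <- counts[counts > 0L]
  total <- sum(counts)
  if (k * size > total)
    stop("k * size (", k * size, ") exceeds sample total (", total, ")")
  old <- withr_seed(seed)
  on.exit(restore_seed(old))
  tokens <- sample.int(total, k * size)
  breaks <- c(0L, cumsum(counts))
  lapply(seq_len(k), function(j) {
    tok <- tokens[((j - 1) * size + 1):(j * size)]
    drawn <- tabulate(findInterval(tok, breaks, left.open = TRUE),
                      nbins = length(counts))
    keep <- drawn > 0L
    count_table(matrix(as.integer(drawn[keep]), ncol = 1,
                       dimnames = list(base::names(counts)[keep], names[j])))
  })
}

#' Subsampling test of spatial separation
#'
#' Draws three subsamples of `size` reads from one source sample (the
#' "within" group: replicates of a single spatial location, so any
#' dissimilarity is pure sampling noise) and one subsample of `size` reads
#' from each of three other samples (the "across" group). If dissimilarity
#' between the original samples were mere sampling noise, the two groups
#' would look alike; genuinely spatial structure shows up as more unshared
#' and fewer shared OTUs in the across group.
#'
#' Data-point bookkeeping per occupancy class: the shared-by-2 class uses
#' the 3 subsample pairs of each group, the unshared class the 3
#' subsamples of each group, and the shared-by-3 class has a single point
#' per group (no test; reported only).
#'
#' The three within-group subsamples are drawn as a joint partition of
#' `3 * size` reads of the source sample by default (`disjoint = TRUE`).
#' Disjoint subsamples of an exchangeable read pool are independent
#' multinomial draws, so under a no-spatial-structure null the within
#' and across groups are exactly exchangeable and the test is calibrated.
#' `disjoint = FALSE` draws the three subsamples independently with
#' overlap allowed; overlapping subsamples share physical reads and are
#' positively correlated, which biases the within group toward
#' similarity even under the null.
#'
#' @param x a [count_table()].
#' @param within sample id supplying the three within-group subsamples
#'   (needs `3 * size` reads when `disjoint = TRUE`).
#' @param across exactly three sample ids, one subsample each.
#' @param size subsample depth (default 28000).
#' @param seed RNG seed.
#' @param disjoint partition the within source (default) or draw the
#'   three subsamples independently.
#' @return list with `within`, `across` (each: per-class data points and
#'   the group [venn_summary()]), `tests` (data.frame of per-class
#'   two-sample t-tests with direction flags), and `p`/`significant`
#'   (the primary unshared-class verdict).
#' @export
spatial_separation_test <- function(x, within, across, size = 28000, seed = 1,
                                    disjoint = TRUE) {
  validate_count_table(x)
  if (length(across) != 3) stop("exactly 3 across-sample ids required")
  totals <- sample_totals(x)
  need <- c(within, across)
  if (any(totals[need] < size))
    stop("insufficient depth for subsample size ", size, ": ",
         paste(need[totals[need] < size], collapse = ", "))
  if (disjoint && totals[within] < 3 * size)
    stop("disjoint design needs 3 * size = ", 3 * size, " reads in ", within)

  subs_within <- if (disjoint) {
    disjoint_subsamples(x, within, size, k = 3, seed = seed * 1000L,
                        names = paste0(within, "_sub", 1:3))
  } else {
    lapply(1:3, function(i)
      subsample_reads(x, within, size, seed = seed * 1000L + i,
                      name = paste0(within, "_sub", i)))
  }
  subs_across <- lapply(seq_along(across), function(i)
    subsample_reads(x, across[i], size, seed = seed * 1000L + 100L + i,
                    name = paste0(across[i], "_r")))

  group_points <- function(tables) {
    tb <- merge_tables(tables)
    vs <- venn_summary(tb)
    per <- vs$per_subset
    list(venn = vs,
         unshared = per$pct[per$k == 1],
         shared_2 = per$pct[per$k == 2],
         shared_3 = per$pct[per$k == 3])
  }
  gw <- group_points(subs_within)
  ga <- group_points(subs_across)

  run_t <- function(o, a) {
    tt <- stats::t.test(o, a, var.equal = TRUE)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }
  tests <- rbind(
    cbind(class = "unshared", run_t(gw$unshared, ga$unshared),
          mean_within = mean(gw$unshared), mean_across = mean(ga$unshared)),
    cbind(class = "shared_2", run_t(gw$shared_2, ga$shared_2),
          mean_within = mean(gw$shared_2), mean_across = mean(ga$shared_2)))
  tests$direction <- ifelse(tests$mean_across > tests$mean_within,
                            "across>within", "across<=within")

  # the unshared class is the primary endpoint: its three data points per
  # group are one per subsample, whereas the pairwise-class points share
  # subsamples and are positively correlated
  primary_p <- tests$p[tests$class == "unshared"]
  list(within = gw, across = ga, tests = tests,
       shared_3 = c(within = gw$shared_3, across = ga$shared_3),
       p = primary_p, significant = primary_p < 0.05,
       size = size, seed = seed)
}

#' Likelihood-ratio chi-squared (G) test of compositional homogeneity
#'
#' `G = 2 sum O_ij log(O_ij / E_ij)` over cells with positive observed
#' counts (zero cells contribute 0, the x log x limit), with expected
#' counts from the usual independence margins and
#' `df = (rows - 1)(cols - 1)`. The statistic is compared to the
#' upper-alpha chi-square critical value; all-zero rows or columns are
#' dropped with a warning before computing df.
#'
#' @param x a [count_table()] (typically phylum-by-sample).
#' @param alpha significance level (default 0.008, a Bonferroni-corrected
#'   0.05 over 6 pairwise comparisons).
#' @return list with `G`, `df`, `alpha`, `critical`, `p`, `significant`.
#' @export
g_test <- function(x, alpha = 0.008) {
  m <- unclass(x)
  drop_r <- rowSums(m) == 0; drop_c <- colSums(m) == 0
  if (any(drop_r) || any(drop_c)) {
    warning("dropping ", sum(drop_r), " empty rows and ", sum(drop_c),
            " empty columns")
    m <- m[!drop_r, !drop_c, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 rows and >= 2 columns")
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  pos <- m > 0
  G <- 2 * sum(m[pos] * log(m[pos] / E[pos]))
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  critical <- stats::qchisq(1 - alpha, df)
  p <- stats::pchisq(G, df, lower.tail = FALSE)
  list(G = G, df = df, alpha = alpha, critical = critical, p = p,
       significant = G > critical)
}

#' Rarefaction curve by resampling without replacement
#'
#' Mean observed OTU count over `reps` seeded without-replacement
#' subsamples at each grid depth. The curve is monotone non-decreasing in
#' expectation and reaches the sample's observed richness exactly at full
#' depth.
#'
#' @param x a [count_table()].
#' @param sample sample id.
#' @param grid depths at which to evaluate (default: 10 points up to the
#'   sample total).
#' @param reps resamples per depth (default 10).
#' @param seed RNG seed.
#' @return data.frame with depth, mean_otus, sd_otus.
#' @export
rarefaction_curve <- function(x, sample, grid = NULL, reps = 10, seed = 1) {
  validate_count_table(x)
  if (!sample %in% colnames(x)) stop("unknown sample id: ", sample)
  total <- sum(unclass(x)[, sample])
  if (is.null(grid)) grid <- unique(round(seq(1, total, length.out = 10)))
  if (any(grid > total)) stop("grid depth exceeds sample total")
  rows <- lapply(grid, function(d) {
    otus <- vapply(seq_len(reps), function(r) {
      sub <- subsample_reads(x, sample, d, seed = seed * 100000L + d %% 7919L * 100L + r)
      nrow(sub)
    }, 0L)
    data.frame(depth = d, mean_otus = mean(otus),
               sd_otus = if (reps > 1) stats::sd(otus) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Exact expected rarefaction richness (hypergeometric closed form)
#'
#' `E[S(d)] = sum_i (1 - choose(N - n_i, d) / choose(N, d))` — the exact
#' expectation that [rarefaction_curve()] approaches as `reps` grows.
#'
#' @inheritParams rarefaction_curve
#' @param depth subsample depth.
#' @export
rarefaction_expected <- function(x, sample, depth) {
  counts <- unclass(x)[, sample]
  counts <- counts[counts > 0]
  N <- sum(counts)
  stopifnot(depth <= N)
  # lchoose for numerical stability at amplicon depths
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Regression of ordination distance on community similarity
#'
#' Given 2-D ordination coordinates (e.g. from NMDS) and the pairwise
#' similarities that produced them, regresses the pairwise Euclidean
#' distance on similarity by ordinary least squares and reports the
#' squared Pearson correlation as the variance explained.
#'
#' @param coordinates matrix or data.frame with 2 columns and one row per
#'   community (row names = sample ids).
#' @param similarities symmetric similarity matrix with matching
#'   dimnames, or a data.frame `s1, s2, value` as returned in
#'   `pairwise_matrix()$pairs`.
#' @return list with `pairs` (s1, s2, distance, similarity), `r2`,
#'   `intercept`, `slope`.
#' @export
embedding_r2 <- function(coordinates, similarities) {
  coords <- as.matrix(coordinates)
  if (ncol(coords) != 2) stop("coordinates must have exactly 2 columns")
  if (nrow(coords) < 3) stop("need at least 3 points")
  ids <- rownames(coords)
  if (is.null(ids)) stop("coordinates must have row names (sample ids)")
  if (is.data.frame(similarities) && all(c("s1", "s2", "value") %in% names(similarities))) {
    sim <- matrix(NA_real_, nrow(coords), nrow(coords), dimnames = list(ids, ids))
    for (i in seq_len(nrow(similarities)))
      sim[similarities$s1[i], similarities$s2[i]] <-
        sim[similarities$s2[i], similarities$s1[i]] <- similarities$value[i]
  } else {
    sim <- as.matrix(similarities)[ids, ids]
  }
  prs <- utils::combn(ids, 2)
  d <- numeric(ncol(prs)); s <- numeric(ncol(prs))
  for (i in seq_len(ncol(prs))) {
    d[i] <- sqrt(sum((coords[prs[1, i], ] - coords[prs[2, i], ])^2))
    s[i] <- sim[prs[1, i], prs[2, i]]
    if (is.na(s[i])) stop("missing similarity for pair ", prs[1, i], "/", prs[2, i])
  }
  if (stats::sd(s) == 0) stop("constant similarity vector: r2 undefined")
  fit <- stats::lm(d ~ s)
  list(pairs = data.frame(s1 = prs[1, ], s2 = prs[2, ], distance = d,
                          similarity = s, stringsAsFactors = FALSE),
       r2 = stats::cor(d, s)^2,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}
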