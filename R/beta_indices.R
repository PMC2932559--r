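#' Presence/absence summary of a sample pair
#'
#' Counts `a` OTUs present (count > 0) in both samples, `b` present only in
#' the first, `c` present only in the second — the substrate of the
#' qualitative similarity indices.
#'
#' @param x a [count_table()].
#' @param s1,s2 distinct sample ids of `x`.
#' @return list with a, b, c.
#' @export
presence_pair <- function(x, s1, s2) {
  validate_count_table(x)
  missing <- setdiff(c(s1, s2), colnames(x))
  if (length(missing)) stop("unknown sample id: ", paste(missing, collapse = ", "))
  if (identical(s1, s2)) stop("s1 and s2 must differ")
  p <- unclass(x)[, s1] > 0L
  q <- unclass(x)[, s2] > 0L
  list(a = sum(p & q), b = sum(p & !q), c = sum(!p & q))
}

#' Qualitative (presence/absence) similarity indices
#'
#' Jaccard `a/(a+b+c)`, Sorensen `2a/(2a+b+c)`, Ochiai
#' `a/sqrt((a+b)(a+c))`, Anderberg `a/(a+2(b+c))`. All lie in `[0,1]`,
#' equal 1 for identical membership and 0 for disjoint membership, and obey
#' the identities `sorensen = 2J/(1+J)` and `anderberg = J/(2-J)`.
#'
#' @param p a presence pair from [presence_pair()], or a list with a, b, c.
#' @return named numeric vector: anderberg, jaccard, sorensen, ochiai.
#' @export
qualitative_indices <- function(p) {
  a <- p$a; b <- p$b; cc <- p$c
  if (a + b + cc == 0) stop("no OTUs present in either sample")
  if (a + b == 0 || a + cc == 0)
    stop("empty sample: Ochiai undefined when one sample has no OTUs")
  c(anderberg = a / (a + 2 * (b + cc)),
    jaccard   = a / (a + b + cc),
    sorensen  = 2 * a / (2 * a + b + cc),
    ochiai    = a / sqrt((a + b) * (a + cc)))
}

#' Sorensen index implied by a Jaccard index
#'
#' The one-to-one identity `S = 2J/(1+J)` linking the two
#' presence/absence indices.
#'
#' @param j Jaccard index in `[0,1]`.
#' @export
sorensen_from_jaccard <- function(j) {
  stopifnot(all(j >= 0 & j <= 1))
  2 * j / (1 + j)
}

#' Anderberg index implied by a Jaccard index (`A = J/(2-J)`)
#' @inheritParams sorensen_from_jaccard
#' @export
anderberg_from_jaccard <- function(j) {
  stopifnot(all(j >= 0 & j <= 1))
  j / (2 - j)
}

# Chao bias-corrected shared-relative-abundance estimators U, V.
# f_plus1 / f_plus2: shared OTUs that are singletons / doubletons in the
# OTHER sample; when f_plus2 = 0 the standard continuity substitution
# f_plus2 <- 1 applies.
chao_uv <- function(xs, ys, bias_correct = TRUE) {
  n <- sum(xs); m <- sum(ys)
  shared <- xs > 0L & ys > 0L
  U <- sum(xs[shared]) / n
  V <- sum(ys[shared]) / m
  if (bias_correct) {
    f_p1 <- sum(shared & ys == 1L); f_p2 <- max(sum(shared & ys == 2L), 1L)
    g_p1 <- sum(shared & xs == 1L); g_p2 <- max(sum(shared & xs == 2L), 1L)
    U <- U + ((m - 1) / m) * (f_p1 / (2 * f_p2)) * sum(xs[shared & ys == 1L]) / n
    V <- V + ((n - 1) / n) * (g_p1 / (2 * g_p2)) * sum(ys[shared & xs == 1L]) / m
  }
  c(U = min(U, 1), V = min(V, 1))
}

#' Quantitative (abundance-weighted) similarity indices
#'
#' Bray-Curtis on raw counts `2 * sum(min(x, y)) / (n + m)` (or on relative
#' abundances with `relative = TRUE`); Chao abundance-based Jaccard
#' `UV/(U+V-UV)` and Sorensen `2UV/(U+V)` built from the (optionally
#' bias-corrected) shared-abundance estimators U, V; Smith theta, the
#' plug-in estimator of `sum(p*q) / (sum(p^2)+sum(q^2)-sum(p*q))`; and
#' Yue-Clayton theta, the same ratio with unbiased moment estimators of
#' the squared terms and cross term.
#'
#' @param x a [count_table()].
#' @param s1,s2 distinct sample ids with positive read totals.
#' @param chao_bias_correct apply the Chao singleton/doubleton correction
#'   to U and V (default TRUE).
#' @param bray_relative compute Bray-Curtis on relative abundances instead
#'   of raw counts.
#' @return named numeric vector: bray_curtis, abund_jaccard,
#'   abund_sorensen, theta_smith, theta_yc — all clamped to `[0,1]`.
#' @export
quantitative_indices <- function(x, s1, s2, chao_bias_correct = TRUE,
                                 bray_relative = FALSE) {
  validate_count_table(x)
  missing <- setdiff(c(s1, s2), colnames(x))
  if (length(missing)) stop("unknown sample id: ", paste(missing, collapse = ", "))
  xs <- as.numeric(unclass(x)[, s1])
  ys <- as.numeric(unclass(x)[, s2])
  n <- sum(xs); m <- sum(ys)
  if (n == 0 || m == 0) stop("sample with zero reads")

  bc <- if (bray_relative) {
    sum(pmin(xs / n, ys / m))
  } else {
    2 * sum(pmin(xs, ys)) / (n + m)
  }

  uv <- chao_uv(xs, ys, chao_bias_correct)
  U <- uv[["U"]]; V <- uv[["V"]]
  if (U + V == 0) {
    aj <- 0; as_ <- 0
  } else {
    aj <- min(max(U * V / (U + V - U * V), 0), 1)
    as_ <- min(max(2 * U * V / (U + V), 0), 1)
  }

  p <- xs / n; q <- ys / m
  cross <- sum(p * q)
  denom_s <- sum(p^2) + sum(q^2) - cross
  smith <- if (denom_s == 0) 0 else cross / denom_s

  p2 <- sum(xs * (xs - 1)) / (n * (n - 1))
  q2 <- sum(ys * (ys - 1)) / (m * (m - 1))
  pq <- sum(xs * ys) / (n * m)
  denom_yc <- p2 + q2 - pq
  yc <- if (pq == 0) 0 else if (denom_yc <= 0) 1 else min(max(pq / denom_yc, 0), 1)

  c(bray_curtis = bc, abund_jaccard = aj, abund_sorensen = as_,
    theta_smith = smith, theta_yc = yc)
}

beta_index_names <- c("anderberg", "jaccard", "sorensen", "ochiai",
                      "bray_curtis", "abund_jaccard", "abund_sorensen",
                      "theta_smith", "theta_yc")

#' One similarity index for one sample pair
#'
#' @inheritParams quantitative_indices
#' @param index one of anderberg, jaccard, sorensen, ochiai, bray_curtis,
#'   abund_jaccard, abund_sorensen, theta_smith, theta_yc.
#' @param ... passed to [quantitative_indices()] for the quantitative
#'   indices.
#' @export
pair_similarity <- function(x, s1, s2, index, ...) {
  index <- match.arg(index, beta_index_names)
  if (index %in% c("anderberg", "jaccard", "sorensen", "ochiai")) {
    qualitative_indices(presence_pair(x, s1, s2))[[index]]
  } else {
    quantitative_indices(x, s1, s2, ...)[[index]]
  }
}

#' All pairwise values of one index, with the mean and SD over pairs
#'
#' The mean and standard deviation (sample, n-1 denominator) are taken
#' over the `choose(k, 2)` unordered pairs — the convention used when a
#' study reports "index = mean +/- sd of all possible pairwise
#' comparisons".
#'
#' @inheritParams pair_similarity
#' @return list with `matrix` (symmetric, unit diagonal), `pairs`
#'   (data.frame s1, s2, value), `mean`, `sd`.
#' @export
pairwise_matrix <- function(x, index, ...) {
  validate_count_table(x)
  smp <- colnames(x)
  if (length(smp) < 2) stop("need at least 2 samples")
  k <- length(smp)
  mat <- matrix(1, k, k, dimnames = list(smp, smp))
  prs <- utils::combn(smp, 2)
  vals <- numeric(ncol(prs))
  for (i in seq_len(ncol(prs))) {
    v <- pair_similarity(x, prs[1, i], prs[2, i], index, ...)
    vals[i] <- v
    mat[prs[1, i], prs[2, i]] <- v
    mat[prs[2, i], prs[1, i]] <- v
  }
  list(matrix = mat,
       pairs = data.frame(s1 = prs[1, ], s2 = prs[2, ], value = vals,
                          stringsAsFactors = FALSE),
       mean = mean(vals),
       # a single pair is reported with zero spread
       sd = if (length(vals) > 1) stats::sd(vals) else 0)
}

#' Shared-OTU (Venn) accounting over k samples
#'
#' `occupancy` counts OTUs present in exactly each non-empty sample subset
#' (a partition of the distinct OTUs). The sharing percentages follow the
#' inclusive convention: an OTU counts as "shared between the x samples of
#' subset Q" whenever it is present in all of Q, regardless of additional
#' samples, and the denominator is the number of distinct OTUs observed
#' across Q. The unshared ("1 quad") percentage of a sample is its
#' exclusive OTUs over its observed richness. With
#' `denominator = "global"` all percentages are instead taken over the
#' distinct OTUs of the full union. `weight = "clones"` repeats the
#' accounting weighted by reads instead of OTUs.
#'
#' @param x a [count_table()].
#' @param samples sample ids (default: all); 2-4 typical, general k
#'   supported.
#' @param weight count OTUs (`"otus"`) or reads (`"clones"`).
#' @param denominator `"subset"` (inclusive, per-subset) or `"global"`.
#' @return list with `occupancy` (named by subset, e.g. `"q1+q3"`),
#'   `k_shared` (data.frame: k, mean, sd, n_subsets of the inclusive
#'   percentages), `per_subset` (data.frame with every subset's inclusive
#'   percentage), `total_otus`, and `weight`.
#' @export
venn_summary <- function(x, samples = sample_ids(x), weight = c("otus", "clones"),
                         denominator = c("subset", "global")) {
  weight <- match.arg(weight)
  denominator <- match.arg(denominator)
  validate_count_table(x)
  missing <- setdiff(samples, colnames(x))
  if (length(missing)) stop("unknown sample id: ", paste(missing, collapse = ", "))
  m <- unclass(x)[, samples, drop = FALSE]
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  k <- length(samples)
  pres <- m > 0L
  w <- if (weight == "otus") rep(1, nrow(m)) else rowSums(m)

  # exact-occupancy partition
  key <- apply(pres, 1, function(z) paste(samples[z], collapse = "+"))
  occupancy <- tapply(w, key, sum)

  total <- sum(w)
  global_den <- total

  per_subset <- list()
  for (size in seq_len(k)) {
    subs <- utils::combn(samples, size, simplify = FALSE)
    for (Q in subs) {
      in_all <- rowSums(pres[, Q, drop = FALSE]) == size
      if (size == 1) {
        # unshared: exclusive to this sample / its observed richness
        excl <- in_all & rowSums(pres) == 1
        num <- sum(w[excl])
        den <- if (denominator == "subset") sum(w[pres[, Q]]) else global_den
      } else {
        num <- sum(w[in_all])
        den <- if (denominator == "subset")
          sum(w[rowSums(pres[, Q, drop = FALSE]) > 0]) else global_den
      }
      per_subset[[length(per_subset) + 1]] <- data.frame(
        k = size, subset = paste(Q, collapse = "+"),
        numerator = num, denominator = den,
        pct = if (den > 0) 100 * num / den else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per_subset <- do.call(rbind, per_subset)
  k_shared <- do.call(rbind, lapply(split(per_subset, per_subset$k), function(d)
    data.frame(k = d$k[1], mean = mean(d$pct),
               sd = if (nrow(d) > 1) stats::sd(d$pct) else NA_real_,
               n_subsets = nrow(d))))
  rownames(k_shared) <- NULL
  list(occupancy = as.list(occupancy), k_shared = k_shared,
       per_subset = per_subset, total_otus = total, weight = weight,
       denominator = denominator)
}
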