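#' Frequency counts of a sample's OTU abundances
#'
#' The abundance frequency data `f(k)` = number of OTUs observed exactly
#' `k` times, with observed richness `D = sum(f)` and read total
#' `N = sum(k * f(k))` — the substrate of the parametric richness model.
#'
#' @param x a [count_table()].
#' @param sample sample id.
#' @return list with `f` (named integer vector over observed k), `D`, `N`.
#' @export
frequency_counts <- function(x, sample) {
  validate_count_table(x)
  if (!sample %in% colnames(x)) stop("unknown sample id: ", sample)
  counts <- unclass(x)[, sample]
  counts <- counts[counts > 0L]
  tab <- table(counts)
  f <- stats::setNames(as.integer(tab), names(tab))
  list(f = f, D = sum(f), N = sum(as.integer(names(f)) * f))
}

# Geometric pmf arising from exponential(mean mu) mixing of Poisson rates:
# P(X = k) = (1/(1+mu)) * (mu/(1+mu))^k, k >= 0
geom_mix_pmf <- function(k, mu) (1 / (1 + mu)) * (mu / (1 + mu))^k

mixture_pmf <- function(k, w, mu1, mu2) {
  w * geom_mix_pmf(k, mu1) + (1 - w) * geom_mix_pmf(k, mu2)
}

mixture_p0 <- function(w, mu1, mu2) mixture_pmf(0, w, mu1, mu2)

# P(X > tau) for the two-component geometric mixture: the geometric tail
# P(X > tau) = (mu/(1+mu))^(tau+1)
mixture_tail <- function(tau, w, mu1, mu2) {
  w * (mu1 / (1 + mu1))^(tau + 1) + (1 - w) * (mu2 / (1 + mu2))^(tau + 1)
}

# negative zero-truncated multinomial log-likelihood of frequencies f(k),
# k = 1..tau, with counts > tau pooled into one tail cell
neg_loglik_mixture <- function(par, ks, fs, f_tail, tau) {
  w <- stats::plogis(par[1]); mu1 <- exp(par[2]); mu2 <- exp(par[3])
  p0 <- mixture_p0(w, mu1, mu2)
  denom <- 1 - p0
  if (denom <= 0) return(1e12)
  pk <- mixture_pmf(ks, w, mu1, mu2)
  if (any(pk <= 0)) return(1e12)
  ll <- sum(fs * log(pk))
  if (f_tail > 0) {
    pt <- mixture_tail(tau, w, mu1, mu2)
    if (pt <= 0) return(1e12)
    ll <- ll + f_tail * log(pt)
  }
  ll <- ll - (sum(fs) + f_tail) * log(denom)
  -ll
}

#' Fit the mixture-of-two-exponentials mixed-Poisson richness model
#'
#' Under an exponential(mean mu) mixing distribution a mixed-Poisson count
#' is geometric, so the marginal count law is a two-component geometric
#' mixture `P(k) = w g(k; mu1) + (1-w) g(k; mu2)` with
#' `g(k; mu) = (1/(1+mu)) (mu/(1+mu))^k`. Parameters maximise the
#' zero-truncated multinomial likelihood of the frequencies `f(k)` for
#' `k <= tau`, with counts above the truncation point pooled into one tail
#' cell. Estimated total richness is
#' `S_hat = D_tau / (1 - P(0)) + (OTUs above tau)`.
#'
#' Optimisation is multi-start quasi-Newton (BFGS after Nelder-Mead
#' polish) on transformed parameters (logit w, log mu1, log mu2) from 10
#' deterministic seeded starts. A degenerate mixture (w within 0.005 of 0
#' or 1, or mu1 = mu2) falls back to a single geometric with
#' `degenerate = TRUE`.
#'
#' `truncation = "auto"` scans the grid {10, 25, 50, 100, max k} and keeps
#' the highest truncation point whose goodness-of-fit chi-square p-value
#' is at least 0.05 (falling back to the best-p point when none passes).
#'
#' @param freq frequency counts from [frequency_counts()] (list with `f`,
#'   `D`, `N`).
#' @param truncation `"auto"` or a positive integer truncation point.
#' @return a `richness_fit` list: `w`, `mu1`, `mu2` (canonical order
#'   mu1 <= mu2), `S_hat`, `D`, `f1_observed`, `tau`, `loglik`,
#'   `gof_chisq`, `gof_df`, `gof_p`, `degenerate`, `p0`.
#' @export
fit_mixed_poisson <- function(freq, truncation = "auto") {
  f <- freq$f
  ks_all <- as.integer(names(f))
  if (identical(truncation, "auto")) {
    grid <- sort(unique(pmin(c(10L, 25L, 50L, 100L, max(ks_all)), max(ks_all))))
    fits <- lapply(grid, function(tau) try(fit_mixed_poisson(freq, tau), silent = TRUE))
    ok <- !vapply(fits, inherits, TRUE, "try-error")
    fits <- fits[ok]; grid <- grid[ok]
    if (!length(fits)) stop("mixture fit failed at every truncation point")
    ps <- vapply(fits, function(ft) ft$gof_p, 0)
    pass <- which(ps >= 0.05)
    pick <- if (length(pass)) pass[which.max(grid[pass])] else which.max(ps)
    return(fits[[pick]])
  }

  tau <- as.integer(truncation)
  in_tau <- ks_all <= tau
  ks <- ks_all[in_tau]; fs <- f[in_tau]
  if (length(ks) < 3) stop("need frequencies at >= 3 distinct counts <= tau")
  f_tail <- sum(f[!in_tau])
  D_tau <- sum(fs)
  D <- freq$D

  # deterministic multi-start on (logit w, log mu1, log mu2)
  mean_k <- sum(ks * fs) / sum(fs)
  starts <- list()
  grid_w <- c(0.3, 0.5, 0.7, 0.9)
  grid_m <- list(c(0.3, mean_k * 2), c(0.5, 50), c(1, mean_k * 5),
                 c(mean_k / 4, mean_k * 4), c(0.1, 10))
  for (w0 in grid_w) for (m in grid_m)
    starts[[length(starts) + 1]] <- c(stats::qlogis(w0), log(m[1]), log(m[2]))
  starts <- starts[seq_len(min(10, length(starts)))]

  best <- NULL
  for (st in starts) {
    fit1 <- try(stats::optim(st, neg_loglik_mixture, ks = ks, fs = fs,
                             f_tail = f_tail, tau = tau,
                             method = "Nelder-Mead",
                             control = list(maxit = 2000, reltol = 1e-10)),
                silent = TRUE)
    if (inherits(fit1, "try-error")) next
    fit2 <- try(stats::optim(fit1$par, neg_loglik_mixture, ks = ks, fs = fs,
                             f_tail = f_tail, tau = tau, method = "BFGS",
                             control = list(maxit = 500, reltol = 1e-12)),
                silent = TRUE)
    cand <- if (inherits(fit2, "try-error")) fit1 else fit2
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best)) stop("mixture fit did not converge from any start")

  w <- stats::plogis(best$par[1]); mu1 <- exp(best$par[2]); mu2 <- exp(best$par[3])
  degenerate <- FALSE
  if (w < 0.005 || w > 0.995 || abs(log(mu1 / mu2)) < 1e-6) {
    # single-geometric fallback: 1-D search on log mu
    nll1 <- function(lmu) neg_loglik_mixture(c(stats::qlogis(0.5), lmu, lmu),
                                             ks, fs, f_tail, tau)
    opt1 <- stats::optimize(nll1, interval = log(c(1e-4, 1e6)))
    mu1 <- mu2 <- exp(opt1$minimum); w <- 1
    best <- list(value = opt1$objective)
    degenerate <- TRUE
  }
  if (mu1 > mu2) { tmp <- mu1; mu1 <- mu2; mu2 <- tmp; w <- 1 - w }

  p0 <- mixture_p0(w, mu1, mu2)
  S_hat <- D_tau / (1 - p0) + f_tail
  if (S_hat < D) S_hat <- D  # estimator floor: richness cannot be below observed

  # goodness of fit on the truncated cells (tail pooled), small expected
  # cells pooled from the right to keep E >= 5 where possible
  denom <- 1 - p0
  probs <- mixture_pmf(ks, w, mu1, mu2) / denom
  obs <- as.numeric(fs)
  if (f_tail > 0 || mixture_tail(tau, w, mu1, mu2) > 0) {
    probs <- c(probs, mixture_tail(tau, w, mu1, mu2) / denom)
    obs <- c(obs, f_tail)
  }
  expd <- (D_tau + f_tail) * probs / sum(probs)
  while (length(expd) > 2 && expd[length(expd)] < 5) {
    n_ <- length(expd)
    expd[n_ - 1] <- expd[n_ - 1] + expd[n_]; obs[n_ - 1] <- obs[n_ - 1] + obs[n_]
    expd <- expd[-n_]; obs <- obs[-n_]
  }
  gof_chisq <- sum((obs - expd)^2 / expd)
  gof_df <- max(length(expd) - 1 - (if (degenerate) 1 else 3), 1)
  gof_p <- stats::pchisq(gof_chisq, gof_df, lower.tail = FALSE)

  f1 <- if ("1" %in% names(f)) unname(f[["1"]]) else 0L
  structure(list(w = w, mu1 = mu1, mu2 = mu2, S_hat = S_hat, D = D,
                 D_tau = D_tau, f1_observed = f1, tau = tau, p0 = p0,
                 loglik = -best$value, gof_chisq = gof_chisq, gof_df = gof_df,
                 gof_p = gof_p, degenerate = degenerate),
            class = "richness_fit")
}

#' @export
print.richness_fit <- function(x, ...) {
  cat(sprintf(
    "richness_fit: w=%.3f mu1=%.3g mu2=%.3g  S_hat=%.0f (D=%d, f1=%d)\n",
    x$w, x$mu1, x$mu2, x$S_hat, x$D, x$f1_observed))
  cat(sprintf("  tau=%d  logLik=%.2f  GOF chisq=%.2f (df=%d, p=%.3g)%s\n",
              x$tau, x$loglik, x$gof_chisq, x$gof_df, x$gof_p,
              if (x$degenerate) "  [single-component fallback]" else ""))
  invisible(x)
}

#' Expected-singleton pool under the fitted richness model
#'
#' The pool from which the shared-singleton null model draws. Default
#' (`method = "not_seen_twice"`): species not yet observed at least twice
#' under a complete census, `N_pool = S_hat - (D - f1)` — the estimated
#' undetected species plus the observed singletons. The alternative
#' (`method = "expected_f1"`) is the model-expected number of singletons
#' at a hypothetical complete census, `S_hat * P(X = 1)`.
#'
#' @param fit a `richness_fit`.
#' @param method `"not_seen_twice"` (default) or `"expected_f1"`.
#' @return pool size (numeric).
#' @export
expected_singleton_pool <- function(fit, method = c("not_seen_twice", "expected_f1")) {
  method <- match.arg(method)
  if (fit$S_hat < fit$D) stop("invalid fit: S_hat < D")
  if (method == "not_seen_twice") {
    fit$S_hat - (fit$D - fit$f1_observed)
  } else {
    fit$S_hat * mixture_pmf(1, fit$w, fit$mu1, fit$mu2)
  }
}

# percentages shared-by-k / unshared from per-species detection prob p,
# under either denominator convention (see venn_summary)
shared_percentages_from_p <- function(p, R, N, denominator) {
  out <- numeric(R)
  names(out) <- c("unshared", paste0("shared_", 2:R))
  for (x in 2:R) {
    num <- N * p^x
    den <- if (denominator == "subset") N * (1 - (1 - p)^x)
           else N * (1 - (1 - p)^R)
    out[paste0("shared_", x)] <- 100 * num / den
  }
  if (denominator == "subset") {
    out["unshared"] <- 100 * (1 - p)^(R - 1)
  } else {
    out["unshared"] <- 100 * (R * p * (1 - p)^(R - 1)) / (R * (1 - (1 - p)^R))
  }
  out
}

#' Predict shared-singleton percentages under the with-replacement null
#'
#' The null model of sampling-driven sharing: each of `R` replicate
#' communities is built by drawing `n` times with replacement from a
#' common pool of `N` equally likely species, so a given pool species is
#' detected in one replicate with probability `p = 1 - (1 - 1/N)^n` and
#' its occupancy across replicates is Binomial(R, p). Closed-form expected
#' occupancy-class counts are `E[exactly k] = N choose(R,k) p^k
#' (1-p)^(R-k)`. Percentages follow the inclusive per-subset convention
#' (`denominator = "subset"`, the default: shared-by-x% =
#' `p^x / (1 - (1-p)^x)`, unshared% = `(1-p)^(R-1)`) or the global-union
#' convention (`denominator = "global"`).
#'
#' With `mc_reps > 0` the literal draws are also simulated and summarised
#' as mean and SD over repetitions.
#'
#' @param N pool size (>= 1).
#' @param n draws per replicate (>= 1).
#' @param R number of replicates (>= 2), default 4.
#' @param denominator `"subset"` or `"global"`.
#' @param mc_reps Monte Carlo repetitions (0 disables simulation).
#' @param seed RNG seed for the Monte Carlo mode.
#' @return list with `p`, `expected_occupancy` (E[exactly k], k = 0..R),
#'   `percentages` (closed form), and `mc` (NULL, or list with `mean`,
#'   `sd`, `reps`, `seed`).
#' @export
predict_shared <- function(N, n, R = 4, denominator = c("subset", "global"),
                           mc_reps = 0, seed = 1) {
  denominator <- match.arg(denominator)
  stopifnot(N >= 1, n >= 1, R >= 2)
  p <- 1 - (1 - 1 / N)^n
  occ <- stats::setNames(N * stats::dbinom(0:R, R, p), paste0("exactly_", 0:R))
  pct <- shared_percentages_from_p(p, R, N, denominator)

  mc <- NULL
  if (mc_reps > 0) {
    res <- matrix(NA_real_, nrow = mc_reps, ncol = length(pct),
                  dimnames = list(NULL, names(pct)))
    old_seed <- withr_seed(seed)
    on.exit(restore_seed(old_seed), add = TRUE)
    for (r in seq_len(mc_reps)) {
      pres <- matrix(FALSE, nrow = N, ncol = R)
      for (j in seq_len(R)) {
        hit <- unique(sample.int(N, n, replace = TRUE))
        pres[hit, j] <- TRUE
      }
      occ_r <- rowSums(pres)
      row <- numeric(length(pct)); names(row) <- names(pct)
      for (x in 2:R) {
        subs <- utils::combn(R, x, simplify = FALSE)
        vals <- vapply(subs, function(Q) {
          num <- sum(rowSums(pres[, Q, drop = FALSE]) == x)
          den <- if (denominator == "subset")
            sum(rowSums(pres[, Q, drop = FALSE]) > 0) else sum(occ_r > 0)
          if (den > 0) 100 * num / den else NA_real_
        }, 0)
        row[paste0("shared_", x)] <- mean(vals, na.rm = TRUE)
      }
      uns <- vapply(seq_len(R), function(j) {
        num <- sum(pres[, j] & occ_r == 1)
        den <- if (denominator == "subset") sum(pres[, j]) else sum(occ_r > 0)
        if (den > 0) 100 * num / den else NA_real_
      }, 0)
      row["unshared"] <- mean(uns, na.rm = TRUE)
      res[r, ] <- row
    }
    mc <- list(mean = colMeans(res), sd = apply(res, 2, stats::sd),
               reps = mc_reps, seed = seed)
  }
  list(p = p, expected_occupancy = occ, percentages = pct,
       denominator = denominator, N = N, n = n, R = R, mc = mc)
}

#' Compare observed and predicted sharing percentages per occupancy class
#'
#' Two-sample Student t-test per class (equal variances), with direction
#' flags for the hypothesis that genuinely spatial structure shows
#' observed unshared above prediction and observed shared below
#' prediction. Classes with fewer than 2 points on either side are
#' skipped with a warning.
#'
#' @param observed named list: class -> numeric vector of observed
#'   percentage data points.
#' @param predicted named list: class -> numeric vector of predicted
#'   percentage data points.
#' @return data.frame with class, mean_observed, mean_predicted, t, df,
#'   p, and direction (`"observed>predicted"` / `"observed<predicted"` /
#'   `"none"`).
#' @export
compare_observed_predicted <- function(observed, predicted) {
  classes <- intersect(names(observed), names(predicted))
  rows <- list()
  for (cl in classes) {
    o <- observed[[cl]]; pr <- predicted[[cl]]
    if (length(o) < 2 || length(pr) < 2) {
      warning("class '", cl, "' skipped: fewer than 2 data points on one side")
      rows[[cl]] <- data.frame(class = cl, mean_observed = mean(o),
                               mean_predicted = mean(pr), t = NA_real_,
                               df = NA_real_, p = NA_real_,
                               direction = "none", stringsAsFactors = FALSE)
      next
    }
    if (stats::sd(o) == 0 && stats::sd(pr) == 0) {
      # degenerate: no within-group variation; equal means are a perfect null
      tt <- list(statistic = if (mean(o) == mean(pr)) 0 else Inf * sign(mean(o) - mean(pr)),
                 parameter = length(o) + length(pr) - 2,
                 p.value = if (mean(o) == mean(pr)) 1 else 0)
    } else {
      tt <- stats::t.test(o, pr, var.equal = TRUE)
    }
    dir <- if (identical(mean(o), mean(pr))) "none"
           else if (mean(o) > mean(pr)) "observed>predicted" else "observed<predicted"
    rows[[cl]] <- data.frame(class = cl, mean_observed = mean(o),
                             mean_predicted = mean(pr),
                             t = unname(tt$statistic), df = unname(tt$parameter),
                             p = tt$p.value, direction = dir,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
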