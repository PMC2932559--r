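# simulate frequency counts directly from the mixed-Poisson model:
# rates from w*Exp(mu1) + (1-w)*Exp(mu2), counts Poisson(rate)
simulate_freq <- function(seed, S, w, mu1, mu2) {
  set.seed(seed)
  comp <- runif(S) < w
  lam <- ifelse(comp, rexp(S, 1 / mu1), rexp(S, 1 / mu2))
  counts <- rpois(S, lam)
  counts <- counts[counts > 0]
  tb <- table(counts)
  list(f = setNames(as.integer(tb), names(tb)), D = length(counts),
       N = sum(counts))
}

test_that("frequency counts satisfy their accounting identities", {
  tb <- random_table(3, n_otu = 40, n_samp = 2, max_count = 30)
  fc <- frequency_counts(tb, "s1")
  expect_equal(sum(fc$f), fc$D)
  expect_equal(sum(as.integer(names(fc$f)) * fc$f), fc$N)
  expect_equal(fc$N, unname(sample_totals(tb)["s1"]))
})

test_that("the geometric mixture is a proper zero-truncated law", {
  for (par in list(c(0.3, 0.5, 8), c(0.7, 1, 40), c(0.5, 2, 2))) {
    w <- par[1]; mu1 <- par[2]; mu2 <- par[3]
    ks <- 0:2000
    total <- sum(finescale:::mixture_pmf(ks, w, mu1, mu2)) +
      finescale:::mixture_tail(2000, w, mu1, mu2)
    expect_equal(total, 1, tolerance = 1e-12)
    # closed-form tail matches direct summation (absolute comparison:
    # the direct sum loses relative precision to cancellation)
    direct <- 1 - sum(finescale:::mixture_pmf(0:20, w, mu1, mu2))
    expect_lt(abs(finescale:::mixture_tail(20, w, mu1, mu2) - direct), 1e-12)
  }
})

test_that("a single geometric community is recovered within 10%", {
  mus <- numeric(10); shats <- numeric(10)
  for (s in 1:10) {
    freq <- simulate_freq(s, S = 2000, w = 1, mu1 = 5, mu2 = 5)
    fit <- fit_mixed_poisson(freq, truncation = "auto")
    # one effective component: either the fallback fired or both
    # components landed on the same mean
    mu_eff <- fit$w * fit$mu1 + (1 - fit$w) * fit$mu2
    mus[s] <- mu_eff; shats[s] <- fit$S_hat
  }
  expect_true(all(abs(mus - 5) / 5 < 0.10))
  expect_true(all(abs(shats - 2000) / 2000 < 0.10))
})

test_that("two-component fits cover the truth at reduced scale", {
  shats <- vapply(1:10, function(s) {
    freq <- simulate_freq(s, S = 2000, w = 0.7, mu1 = 0.5, mu2 = 7.17)
    fit_mixed_poisson(freq, truncation = "auto")$S_hat
  }, 0)
  expect_gte(mean(abs(shats - 2000) / 2000 <= 0.15), 0.8)
})

test_that("singleton pool follows its defining identities", {
  fit <- structure(list(S_hat = 44959, D = 18265, f1_observed = 12140,
                        w = 0.5, mu1 = 1, mu2 = 10),
                   class = "richness_fit")
  expect_equal(expected_singleton_pool(fit), 38834)

  # complete census: pool reduces to the observed singletons
  fit2 <- structure(list(S_hat = 500, D = 500, f1_observed = 60,
                         w = 0.5, mu1 = 1, mu2 = 10), class = "richness_fit")
  expect_equal(expected_singleton_pool(fit2), 60)
  fit3 <- structure(list(S_hat = 500, D = 500, f1_observed = 0,
                         w = 0.5, mu1 = 1, mu2 = 10), class = "richness_fit")
  expect_equal(expected_singleton_pool(fit3), 0)

  # pool is monotone in f1 at fixed S_hat, D
  fit4 <- structure(list(S_hat = 44959, D = 18265, f1_observed = 12141,
                         w = 0.5, mu1 = 1, mu2 = 10), class = "richness_fit")
  expect_equal(expected_singleton_pool(fit4) - expected_singleton_pool(fit), 1)

  bad <- structure(list(S_hat = 100, D = 200, f1_observed = 10),
                   class = "richness_fit")
  expect_error(expected_singleton_pool(bad), "S_hat < D")
})

test_that("the model-expected singleton alternative uses P(X = 1)", {
  fit <- structure(list(S_hat = 1000, D = 600, f1_observed = 200,
                        w = 0.4, mu1 = 0.5, mu2 = 20), class = "richness_fit")
  expect_equal(expected_singleton_pool(fit, "expected_f1"),
               1000 * finescale:::mixture_pmf(1, 0.4, 0.5, 20))
})

test_that("closed-form detection probability and occupancy match hand values", {
  ps <- predict_shared(100, 50, 4)
  expect_equal(ps$p, 1 - 0.99^50, tolerance = 1e-12)
  expect_equal(unname(ps$expected_occupancy["exactly_4"]), 100 * ps$p^4,
               tolerance = 1e-12)
  expect_equal(sum(ps$expected_occupancy), 100, tolerance = 1e-9)

  big <- predict_shared(38834, 12140, 4)
  expect_equal(big$p, 0.268, tolerance = 0.002)

  # deep draws detect everything: unshared vanishes, sharing saturates
  deep <- predict_shared(100, 1e6, 4)
  expect_equal(unname(deep$percentages["unshared"]), 0, tolerance = 1e-9)
  expect_equal(unname(deep$percentages["shared_4"]), 100, tolerance = 1e-6)
})

test_that("Monte Carlo draws agree with the closed form", {
  ps <- predict_shared(200, 80, 4, mc_reps = 400, seed = 42)
  for (cls in names(ps$percentages)) {
    se <- ps$mc$sd[[cls]] / sqrt(ps$mc$reps)
    expect_lt(abs(ps$mc$mean[[cls]] - ps$percentages[[cls]]),
              max(3 * se, 0.5))
  }
  # seeded reproducibility
  ps2 <- predict_shared(200, 80, 4, mc_reps = 50, seed = 9)
  ps3 <- predict_shared(200, 80, 4, mc_reps = 50, seed = 9)
  expect_identical(ps2$mc$mean, ps3$mc$mean)
})

test_that("observed-vs-predicted comparison behaves on degenerate and planted input", {
  same <- list(unshared = c(30, 30, 30), shared_2 = c(10, 10, 10))
  cmp <- compare_observed_predicted(same, same)
  expect_equal(cmp$t, c(0, 0))
  expect_equal(cmp$p, c(1, 1))

  obs <- list(unshared = c(77, 78, 76, 77.5))
  pred <- list(unshared = c(31, 33, 30, 29))
  cmp2 <- compare_observed_predicted(obs, pred)
  expect_lt(cmp2$p, 0.001)
  expect_equal(cmp2$direction, "observed>predicted")

  expect_warning(
    cmp3 <- compare_observed_predicted(list(a = 5), list(a = c(4, 6))),
    "skipped")
  expect_true(is.na(cmp3$p))
})
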