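test_that("subsampling at full depth is the identity", {
  tb <- random_table(8, n_otu = 20, n_samp = 2, max_count = 10)
  total <- sum(unclass(tb)[, "s1"])
  sub <- subsample_reads(tb, "s1", total, seed = 4)
  orig <- unclass(tb)[, "s1"]; orig <- orig[orig > 0]
  expect_equal(unclass(sub)[names(orig), 1], orig)
})

test_that("subsample column sums always equal the requested size", {
  tb <- random_table(9, n_otu = 30, n_samp = 2, max_count = 15)
  for (size in c(1, 5, 17)) {
    sub <- subsample_reads(tb, "s1", size, seed = size)
    expect_equal(sum(sub), size)
  }
  expect_error(subsample_reads(tb, "s1", 10000), "exceeds")
})

test_that("single-read draws follow the abundance-proportional law", {
  m <- matrix(c(60L, 30L, 10L), ncol = 1, dimnames = list(c("a", "b", "c"), "s"))
  tb <- count_table(m)
  draws <- vapply(1:4000, function(i)
    otu_ids(subsample_reads(tb, "s", 1, seed = i)), "")
  obs <- table(factor(draws, levels = c("a", "b", "c")))
  chi <- suppressWarnings(chisq.test(obs, p = c(0.6, 0.3, 0.1)))
  expect_gt(chi$p.value, 0.001)
})

test_that("subsampling is seeded and reproducible", {
  tb <- random_table(10, n_otu = 25, n_samp = 2, max_count = 10)
  a <- subsample_reads(tb, "s1", 10, seed = 77)
  b <- subsample_reads(tb, "s1", 10, seed = 77)
  expect_identical(unclass(a), unclass(b))
})

test_that("disjoint subsamples partition reads of the source", {
  tb <- random_table(12, n_otu = 40, n_samp = 2, max_count = 20)
  total <- sum(unclass(tb)[, "s1"])
  size <- floor(total / 3)
  subs <- disjoint_subsamples(tb, "s1", size, k = 3, seed = 2)
  expect_length(subs, 3)
  for (s in subs) expect_equal(sum(s), size)
  merged <- merge_tables(subs)
  pooled <- rowSums(unclass(merged))
  orig <- unclass(tb)[names(pooled), "s1"]
  expect_true(all(pooled <= orig))
  expect_error(disjoint_subsamples(tb, "s1", total, k = 3), "exceeds")
})

test_that("G statistic matches its closed form and the chi-square reference", {
  hom <- count_table(matrix(c(10L, 10L, 10L, 10L), 2,
                            dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  g0 <- g_test(hom, alpha = 0.05)
  expect_equal(g0$G, 0)
  expect_equal(g0$p, 1)
  expect_false(g0$significant)

  het <- count_table(matrix(c(20L, 10L, 10L, 20L), 2,
                            dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  g1 <- g_test(het, alpha = 0.05)
  expect_equal(g1$G, 6.796, tolerance = 1e-3)
  expect_equal(g1$df, 1L)
  expect_equal(g1$p, pchisq(g1$G, 1, lower.tail = FALSE))

  # the critical value at df = 177, alpha = 0.008 used for phylum tables
  expect_equal(qchisq(1 - 0.008, 177), 225.5, tolerance = 1e-3)

  # proportional rows: G = 0 within numerical noise
  prop <- count_table(matrix(c(30L, 15L, 60L, 30L), 2,
                             dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  expect_lt(g_test(prop, alpha = 0.05)$G, 1e-10)
})

test_that("G test is invariant under row and column permutation", {
  tb <- random_table(13, n_otu = 6, n_samp = 4, max_count = 30)
  g <- g_test(tb, alpha = 0.05)
  perm <- count_table(unclass(tb)[sample(nrow(tb)), sample(ncol(tb))])
  g2 <- g_test(perm, alpha = 0.05)
  expect_equal(g2$G, g$G, tolerance = 1e-12)
  expect_equal(g2$df, g$df)
})

test_that("rarefaction endpoints are exact and the curve is monotone", {
  tb <- random_table(14, n_otu = 50, n_samp = 2, max_count = 10)
  total <- sum(unclass(tb)[, "s1"])
  rich <- sum(unclass(tb)[, "s1"] > 0)
  rc <- rarefaction_curve(tb, "s1", grid = c(1, round(total / 2), total),
                          reps = 5, seed = 3)
  expect_equal(rc$mean_otus[1], 1)
  expect_equal(rc$mean_otus[3], rich)
  expect_true(all(diff(rc$mean_otus) >= 0))
})

test_that("rarefaction matches the exact hypergeometric expectation", {
  m <- matrix(rep(3L, 100), ncol = 1, dimnames = list(sprintf("o%03d", 1:100), "s"))
  tb <- count_table(m)
  exact <- rarefaction_expected(tb, "s", 50)
  reps <- 60
  rc <- rarefaction_curve(tb, "s", grid = 50, reps = reps, seed = 9)
  se <- rc$sd_otus / sqrt(reps)
  expect_lt(abs(rc$mean_otus - exact), 3 * se + 0.5)

  skip_if_not_installed("vegan")
  veg <- suppressWarnings(vegan::rarefy(t(unclass(tb))[1, ], 50))
  expect_equal(exact, as.numeric(veg), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ordination-distance regression recovers perfect linear structure", {
  sim <- matrix(c(1, .9, .4, .9, 1, .5, .4, .5, 1), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # place points so pairwise distance is exactly 1 - similarity
  d_ab <- 1 - .9; d_ac <- 1 - .4; d_bc <- 1 - .5
  x_b <- d_ab
  x_c <- (d_ab^2 + d_ac^2 - d_bc^2) / (2 * d_ab)
  y_c <- sqrt(max(d_ac^2 - x_c^2, 0))
  coords <- rbind(a = c(0, 0), b = c(x_b, 0), c = c(x_c, y_c))
  fit <- embedding_r2(coords, sim)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$slope, -1, tolerance = 1e-9)

  expect_error(embedding_r2(coords, matrix(0.5, 3, 3,
                                           dimnames = dimnames(sim))),
               "constant")
})

test_that("unrelated embeddings explain little variance", {
  set.seed(31)
  r2s <- vapply(1:40, function(i) {
    coords <- matrix(rnorm(12), ncol = 2,
                     dimnames = list(paste0("s", 1:6), NULL))
    sim <- matrix(runif(36), 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
    sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
    diag(sim) <- 1
    embedding_r2(coords, sim)$r2
  }, 0)
  expect_lt(median(r2s), 0.2)
})

test_that("duplicate ordination points contribute zero distance", {
  coords <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  sim <- matrix(c(1, .8, .3, .8, 1, .3, .3, .3, 1), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- embedding_r2(coords, sim)
  expect_equal(fit$pairs$distance[fit$pairs$s1 == "a" & fit$pairs$s2 == "b"], 0)
})

test_that("spatial test orders classes sensibly on an identical source", {
  cm <- generate_community(synthetic_spec(preset = "small", rho = 0, seed = 60))
  st <- spatial_separation_test(cm$table, "q2", c("q1", "q3", "q4"),
                                size = 1200, seed = 3)
  # deep subsamples of a single source: three-way sharing dominates the
  # within group's class percentages
  expect_gt(st$within$shared_3, mean(st$within$unshared))
  expect_named(st$tests, c("class", "t", "df", "p", "mean_within",
                           "mean_across", "direction"))
})

test_that("planted disjoint rare tails are detected as spatial structure", {
  cm <- generate_community(synthetic_spec(preset = "small", rho = 1, seed = 61))
  st <- spatial_separation_test(cm$table, "q2", c("q1", "q3", "q4"),
                                size = 1200, seed = 5)
  expect_true(st$significant)
  expect_gt(mean(st$across$unshared), mean(st$within$unshared))
})
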