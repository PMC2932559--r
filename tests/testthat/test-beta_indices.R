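test_that("presence pair counts strict-positivity co-occurrence", {
  tb <- tiny_table()
  p <- presence_pair(tb, "s1", "s2")
  expect_equal(p, list(a = 1L, b = 1L, c = 1L))
  expect_error(presence_pair(tb, "s1", "nope"), "unknown sample")
  expect_error(presence_pair(tb, "s1", "s1"), "must differ")
})

test_that("qualitative indices match their closed forms", {
  idx <- qualitative_indices(list(a = 1, b = 1, c = 1))
  expect_equal(unname(idx), c(1 / 5, 1 / 3, 1 / 2, 1 / 2),
               tolerance = 1e-12)
  # identical membership of richness r -> all four are 1
  idx1 <- qualitative_indices(list(a = 7, b = 0, c = 0))
  expect_equal(unname(idx1), rep(1, 4))
  expect_error(qualitative_indices(list(a = 0, b = 0, c = 3)), "Ochiai")
})

test_that("quantitative indices match hand-evaluated closed forms", {
  tb <- tiny_table()  # x = (2,1,0), y = (0,1,3)
  q <- quantitative_indices(tb, "s1", "s2", chao_bias_correct = FALSE)
  expect_equal(q[["bray_curtis"]], 2 / 7, tolerance = 1e-12)
  expect_equal(q[["theta_smith"]], (1 / 12) / (5 / 9 + 5 / 8 - 1 / 12),
               tolerance = 1e-12)
  # raw U = 1/3, V = 1/4 -> Jacc = UV/(U+V-UV), Sor = 2UV/(U+V)
  U <- 1 / 3; V <- 1 / 4
  expect_equal(q[["abund_jaccard"]], U * V / (U + V - U * V), tolerance = 1e-12)
  expect_equal(q[["abund_sorensen"]], 2 * U * V / (U + V), tolerance = 1e-12)
})

test_that("identical columns give 1 and disjoint supports give 0 for all nine", {
  m <- matrix(c(4L, 2L, 1L, 4L, 2L, 1L), nrow = 3,
              dimnames = list(paste0("o", 1:3), c("s1", "s2")))
  tb <- count_table(m)
  vals <- c(qualitative_indices(presence_pair(tb, "s1", "s2")),
            quantitative_indices(tb, "s1", "s2"))
  expect_equal(unname(vals), rep(1, 9))

  md <- matrix(c(3L, 2L, 0L, 0L, 0L, 0L, 0L, 5L, 1L, 2L), nrow = 5,
               dimnames = list(paste0("o", 1:5), c("s1", "s2")))
  tbd <- count_table(md)
  vals_d <- c(qualitative_indices(presence_pair(tbd, "s1", "s2")),
              quantitative_indices(tbd, "s1", "s2"))
  expect_equal(unname(vals_d), rep(0, 9))
})

test_that("all nine indices are symmetric in sample order", {
  for (seed in 1:20) {
    tb <- random_table(seed, n_otu = 15, n_samp = 2)
    if (any(sample_totals(tb) == 0)) next
    f <- c(qualitative_indices(presence_pair(tb, "s1", "s2")),
           quantitative_indices(tb, "s1", "s2"))
    r <- c(qualitative_indices(presence_pair(tb, "s2", "s1")),
           quantitative_indices(tb, "s2", "s1"))
    expect_equal(unname(f[c(1:4, 5)]), unname(r[c(1:4, 5)]), tolerance = 1e-12)
    # Chao U/V and the theta estimators swap roles symmetrically
    expect_equal(unname(f[6:9]), unname(r[6:9]), tolerance = 1e-12)
  }
})

test_that("Sorensen and Anderberg are exact functions of Jaccard", {
  for (seed in 1:50) {
    p <- random_presence_pair(seed)
    idx <- qualitative_indices(p)
    expect_equal(idx[["sorensen"]], sorensen_from_jaccard(idx[["jaccard"]]),
                 tolerance = 1e-14)
    expect_equal(idx[["anderberg"]], anderberg_from_jaccard(idx[["jaccard"]]),
                 tolerance = 1e-14)
    expect_true(idx[["anderberg"]] <= idx[["jaccard"]] + 1e-14)
    expect_true(idx[["jaccard"]] <= idx[["sorensen"]] + 1e-14)
    expect_true(idx[["jaccard"]] <= idx[["ochiai"]] + 1e-14)
  }
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  for (seed in 1:10) {
    tb <- random_table(seed, n_otu = 20, n_samp = 4, max_count = 20)
    ours <- pairwise_matrix(tb, "bray_curtis")$matrix
    theirs <- 1 - as.matrix(vegan::vegdist(t(unclass(tb)), method = "bray"))
    expect_equal(ours, theirs, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Yue-Clayton theta converges to Smith theta as depth grows", {
  tb <- random_table(5, n_otu = 20, n_samp = 2, max_count = 10)
  q1 <- quantitative_indices(tb, "s1", "s2")
  big <- count_table(unclass(tb) * 100L)
  q2 <- quantitative_indices(big, "s1", "s2")
  # Smith theta is scale-invariant; theta_yc approaches it
  expect_equal(q2[["theta_smith"]], q1[["theta_smith"]], tolerance = 1e-12)
  expect_lt(abs(q2[["theta_yc"]] - q2[["theta_smith"]]),
            abs(q1[["theta_yc"]] - q1[["theta_smith"]]) + 1e-9)
  expect_equal(q2[["theta_yc"]], q2[["theta_smith"]], tolerance = 0.01)
})

test_that("pairwise matrix averages all unordered pairs and is permutation-stable", {
  tb <- random_table(9, n_otu = 25, n_samp = 4, max_count = 8)
  pm <- pairwise_matrix(tb, "jaccard")
  expect_equal(nrow(pm$pairs), 6L)
  expect_equal(unname(diag(pm$matrix)), rep(1, 4))
  expect_equal(pm$matrix, t(pm$matrix))
  expect_equal(pm$mean, mean(pm$pairs$value))
  expect_equal(pm$sd, sd(pm$pairs$value))

  perm <- count_table(unclass(tb)[, c(3, 1, 4, 2)])
  pm2 <- pairwise_matrix(perm, "jaccard")
  expect_equal(pm2$mean, pm$mean, tolerance = 1e-12)
  expect_equal(pm2$sd, pm$sd, tolerance = 1e-12)

  col1 <- unclass(tb)[, 1]
  col1 <- col1[col1 > 0]
  two <- count_table(cbind(s1 = col1, s_copy = col1))
  pm_id <- pairwise_matrix(two, "jaccard")
  expect_equal(pm_id$mean, 1)
  expect_equal(pm_id$sd, 0)
})

test_that("venn occupancy equals brute-force set enumeration", {
  tb <- count_table(matrix(c(1L, 0L, 2L, 0L, 1L, 3L), nrow = 3,
                           dimnames = list(c("oa", "ob", "oc"), c("A", "B"))))
  vs <- venn_summary(tb)
  expect_equal(vs$occupancy[["A"]], 1)
  expect_equal(vs$occupancy[["B"]], 1)
  expect_equal(vs$occupancy[["A+B"]], 1)
  expect_equal(vs$per_subset$pct[vs$per_subset$k == 2], 100 / 3)

  for (seed in 1:25) {
    tb <- random_table(seed, n_otu = 15, n_samp = 4)
    vs <- venn_summary(tb)
    oracle <- venn_oracle_occupancy(tb)
    expect_equal(sum(unlist(vs$occupancy)), nrow(tb))
    for (key in names(oracle))
      expect_equal(vs$occupancy[[key]], oracle[[key]])
  }
})

test_that("fully shared OTUs give 100% four-way sharing and 0% unshared", {
  m <- matrix(rep(c(3L, 1L, 2L), 4), nrow = 3,
              dimnames = list(paste0("o", 1:3), paste0("q", 1:4)))
  vs <- venn_summary(count_table(m))
  expect_equal(vs$per_subset$pct[vs$per_subset$k == 4], 100)
  expect_equal(vs$per_subset$pct[vs$per_subset$k == 1], rep(0, 4))
})

test_that("clone weighting counts reads instead of OTUs", {
  tb <- tiny_table()
  vs <- venn_summary(tb, weight = "clones")
  # shared OTU o2 carries 2 reads of 7 total
  expect_equal(vs$occupancy[["s1+s2"]], 2)
  expect_equal(vs$total_otus, 7)
  expect_equal(vs$per_subset$pct[vs$per_subset$k == 2], 100 * 2 / 7)
})

test_that("global denominator option uses the union richness", {
  tb <- tiny_table()
  vs <- venn_summary(tb, denominator = "global")
  expect_equal(vs$per_subset$pct[vs$per_subset$k == 2], 100 / 3)
  # unshared percentages: each exclusive OTU over the union of 3
  expect_equal(vs$per_subset$pct[vs$per_subset$k == 1], c(100 / 3, 100 / 3))
})
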