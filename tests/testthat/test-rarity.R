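test_that("proportion-to-count conversion floors correctly", {
  expect_identical(count_cutoff_for_proportion(77361, 0.00004), 3L)
  expect_identical(count_cutoff_for_proportion(51836, 0.00004), 2L)
  expect_identical(count_cutoff_for_proportion(100, 0.005), 0L)
})

test_that("rare and abundant sides partition the observed OTUs", {
  tb <- count_table(matrix(c(1L, 2L, 5L, 11L, 0L, 3L, 1L, 50L), nrow = 4,
                           dimnames = list(paste0("o", 1:4), c("s1", "s2"))))
  rare <- partition_abundance(tb, "s1", 10, "count", "rare")
  ab <- partition_abundance(tb, "s1", 10, "count", "abundant")
  expect_setequal(rare$selected, c("o1", "o2", "o3"))
  expect_setequal(ab$selected, "o4")
  expect_setequal(union(rare$selected, ab$selected), rare$complement |> union(rare$selected))
  expect_setequal(c(rare$selected, ab$selected), c("o1", "o2", "o3", "o4"))

  singles <- partition_abundance(tb, "s1", 1, "count", "rare")
  expect_setequal(singles$selected, "o1")

  # proportion mode, abundant side: every observed s2 OTU exceeds 1%
  # of the 54 reads (the smallest count, 1, is 1.85%)
  ab_p <- partition_abundance(tb, "s2", 0.01, "proportion", "abundant")
  expect_setequal(ab_p$selected, c("o2", "o3", "o4"))
  # at a 10% cutoff only the dominant OTU (50/54) remains abundant
  ab_p10 <- partition_abundance(tb, "s2", 0.10, "proportion", "abundant")
  expect_setequal(ab_p10$selected, "o4")
})

test_that("fraction tables zero the other side and keep totals consistent", {
  tb <- random_table(31, n_otu = 30, n_samp = 4, max_count = 20)
  rare <- fraction_table(tb, 5, "count", "rare")
  ab <- fraction_table(tb, 5, "count", "abundant")
  expect_equal(sum(rare) + sum(ab), sum(tb))
  expect_true(all(unclass(rare)[unclass(rare) > 0] <= 5))
  expect_true(all(unclass(ab)[unclass(ab) > 0] > 5))
})

test_that("percent identity: identical sequences and planted divergence", {
  s <- strrep("ACGT", 30)
  hit <- percent_identity(s, s)
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$alignment_length, 120L)

  # 12 scattered substitutions in a 120-mer: full-length local alignment
  # at about 90% identity
  set.seed(7)
  b <- strsplit(s, "")[[1]]
  pos <- seq(5, 115, by = 10)
  for (i in pos) b[i] <- setdiff(c("A", "C", "G", "T"), b[i])[1]
  mut <- paste(b, collapse = "")
  hit2 <- percent_identity(s, mut)
  expect_gte(hit2$alignment_length, 100)
  expect_equal(hit2$percent_identity, 90, tolerance = 0.03)
})

test_that("percent identity agrees with the brute-force DP oracle on short pairs", {
  set.seed(11)
  for (i in 1:40) {
    n1 <- sample(8:30, 1); n2 <- sample(8:30, 1)
    s1 <- random_seq(n1); s2 <- random_seq(n2)
    impl <- percent_identity(s1, s2)
    orc <- sw_oracle(s1, s2)
    expect_equal(impl$score, orc$score)
    ok <- any(vapply(orc$profiles, function(pr)
      pr[["columns"]] == impl$alignment_length &&
        pr[["matches"]] == impl$matches, TRUE))
    expect_true(ok, info = paste("pair", i))
  }
})

test_that("random unrelated 120-mers rarely align over 100 bp", {
  set.seed(23)
  lens <- vapply(1:20, function(i)
    percent_identity(random_seq(120), random_seq(120))$alignment_length, 0L)
  expect_lt(mean(lens >= 100), 0.2)
})

test_that("rare classification follows the two-stage rule precedence", {
  set.seed(5)
  parent_ab <- random_seq(200)
  parent_ref <- random_seq(200)
  ref <- c(ref1 = parent_ref)
  abundant <- c(ab1 = parent_ab)

  near_ab <- local({ set.seed(6); mutate_oracle(parent_ab, 0.05) })
  near_ref <- local({ set.seed(8); mutate_oracle(parent_ref, 0.05) })
  unrelated <- local({ set.seed(9); random_seq(200) })

  rare <- c(r_nunn = near_ab, r_unn = near_ref, r_un = unrelated)
  cls <- classify_rare(rare, abundant, ref, weights = c(r_nunn = 8, r_unn = 1, r_un = 1))
  lab <- setNames(cls$labels$label, cls$labels$otu_id)
  expect_equal(unname(lab[c("r_nunn", "r_unn", "r_un")]), c("NUNN", "UNN", "UN"))

  # NUNN takes precedence even when the reference is a perfect match
  cls2 <- classify_rare(c(r1 = parent_ab), abundant, c(ref1 = parent_ab))
  expect_equal(cls2$labels$label, "NUNN")

  # read weighting: 8/10 reads in NUNN
  expect_equal(unname(cls$proportions_reads["NUNN"]), 80)
  expect_equal(sum(cls$proportions_reads), 100)
  expect_equal(sum(cls$proportions_otu), 100)

  # precomputed reference identities work in place of sequences
  cls3 <- classify_rare(c(r_unn = near_ref), abundant,
                        reference = c(r_unn = 95))
  expect_equal(cls3$labels$label, "UNN")
  cls4 <- classify_rare(c(r_un = near_ref), abundant,
                        reference = c(r_un = 70))
  expect_equal(cls4$labels$label, "UN")
})

test_that("raising the identity threshold never increases the NUNN count", {
  set.seed(41)
  parents <- setNames(replicate(3, random_seq(150)), paste0("ab", 1:3))
  rare <- setNames(vapply(seq(0, 0.3, length.out = 6), function(r)
    mutate_oracle(parents[[1]], r), ""), paste0("r", 1:6))
  ref <- c(ref1 = random_seq(150))
  counts <- vapply(c(80, 85, 90, 95, 99), function(th) {
    cls <- classify_rare(rare, parents, ref, min_identity = th)
    sum(cls$labels$label == "NUNN")
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("rare/abundant disjointness is enforced", {
  expect_error(classify_rare(c(x = "ACGT"), c(x = "ACGT"), c(r = "ACGT")),
               "disjoint")
})
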