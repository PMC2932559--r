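# Fixtures and independent oracles used across the test files.

tiny_table <- function() {
  count_table(matrix(c(2L, 1L, 0L, 0L, 1L, 3L), nrow = 3,
                     dimnames = list(c("o1", "o2", "o3"), c("s1", "s2"))))
}

# random small OTU-by-sample table; every OTU observed somewhere
random_table <- function(seed, n_otu = 12, n_samp = 4, max_count = 5) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_otu * n_samp, 0.8), nrow = n_otu,
                dimnames = list(sprintf("o%02d", seq_len(n_otu)),
                                sprintf("s%d", seq_len(n_samp))))
    m[m > max_count] <- max_count
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) >= 2 && all(colSums(m) > 0)) break
  }
  storage.mode(m) <- "integer"
  count_table(m)
}

random_presence_pair <- function(seed) {
  set.seed(seed)
  repeat {
    a <- rpois(1, 5); b <- rpois(1, 3); cc <- rpois(1, 3)
    if (a + b > 0 && a + cc > 0) return(list(a = a, b = b, c = cc))
  }
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")

# independent point-mutator: substitutes each base with probability `rate`
# to one of the three alternatives
mutate_oracle <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

# --- brute-force affine-gap Smith-Waterman oracle ----------------------
# match +1, mismatch -1; a gap of length L costs 1 + L (first gap column
# -2, each further column -1). Returns the optimal local score and the
# set of (matches, columns) profiles attainable by optimal alignments,
# so tie-broken implementations can be checked without fixing a path.
sw_oracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in s2 (consume a)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in s1 (consume b)
  M[1, ] <- NEG; M[, 1] <- NEG
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (a[i - 1] == b[j - 1]) 1 else -1
      M[i, j] <- sub + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0)
      X[i, j] <- max(M[i - 1, j] - 2, X[i - 1, j] - 1, Y[i - 1, j] - 2)
      Y[i, j] <- max(M[i, j - 1] - 2, Y[i, j - 1] - 1, X[i, j - 1] - 2)
      best <- max(best, M[i, j])
    }
  }
  if (best <= 0) return(list(score = 0, profiles = list(c(matches = 0, columns = 0))))

  # enumerate (matches, columns) profiles of all optimal alignments by
  # backward traversal from every optimal M end-cell
  profiles <- new.env(parent = emptyenv())
  add_profile <- function(mt, cols) assign(paste(mt, cols), TRUE, envir = profiles)
  walk <- function(i, j, state, mt, cols) {
    if (state == "M") {
      sub <- if (a[i - 1] == b[j - 1]) 1 else -1
      mt2 <- mt + (sub == 1); cols2 <- cols + 1
      prev <- M[i, j] - sub
      if (abs(prev - 0) < 1e-9) add_profile(mt2, cols2)
      if (i > 2 && j > 2) {
        if (abs(M[i - 1, j - 1] - prev) < 1e-9) walk(i - 1, j - 1, "M", mt2, cols2)
        if (abs(X[i - 1, j - 1] - prev) < 1e-9) walk(i - 1, j - 1, "X", mt2, cols2)
        if (abs(Y[i - 1, j - 1] - prev) < 1e-9) walk(i - 1, j - 1, "Y", mt2, cols2)
      }
    } else if (state == "X") {
      cols2 <- cols + 1
      if (i > 2) {
        if (abs(M[i - 1, j] - 2 - X[i, j]) < 1e-9) walk(i - 1, j, "M", mt, cols2)
        if (abs(X[i - 1, j] - 1 - X[i, j]) < 1e-9) walk(i - 1, j, "X", mt, cols2)
        if (abs(Y[i - 1, j] - 2 - X[i, j]) < 1e-9) walk(i - 1, j, "Y", mt, cols2)
      }
    } else {
      cols2 <- cols + 1
      if (j > 2) {
        if (abs(M[i, j - 1] - 2 - Y[i, j]) < 1e-9) walk(i, j - 1, "M", mt, cols2)
        if (abs(Y[i, j - 1] - 1 - Y[i, j]) < 1e-9) walk(i, j - 1, "Y", mt, cols2)
        if (abs(X[i, j - 1] - 2 - Y[i, j]) < 1e-9) walk(i, j - 1, "X", mt, cols2)
      }
    }
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1))
    if (abs(M[i, j] - best) < 1e-9) walk(i, j, "M", 0, 0)
  keys <- ls(envir = profiles)
  list(score = best,
       profiles = lapply(strsplit(keys, " "), function(z)
         c(matches = as.integer(z[1]), columns = as.integer(z[2]))))
}

# --- brute-force Venn occupancy oracle ---------------------------------
venn_oracle_occupancy <- function(tb) {
  m <- unclass(tb)
  smp <- colnames(m)
  out <- list()
  for (i in seq_len(nrow(m))) {
    pres <- smp[m[i, ] > 0]
    key <- paste(pres, collapse = "+")
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + 1
  }
  out
}
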