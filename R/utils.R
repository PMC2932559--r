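# Local RNG scoping: set a seed for a reproducible block and restore the
# caller's RNG state afterwards, so seeded package internals never perturb
# the user's random stream.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

random_dna <- function(n, length, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, length, replace = TRUE), collapse = ""), "")
}

# point substitutions at exactly round(length * rate) distinct positions,
# each to one of the three alternative bases, so the realised ungapped
# identity is 1 - rate up to rounding (local-alignment end trimming can
# raise the measured identity slightly)
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- min(round(length(bases) * rate), length(bases))
  hit <- sample.int(length(bases), n_mut)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}
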