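# RNG helpers: every stochastic operation runs under a local seed so the
# caller's RNG state is never disturbed and identical seeds give
# byte-identical output.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Split one user-facing seed into independent sub-seeds, one per stream.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

random_dna <- function(n) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)],
        collapse = "")
}
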