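# Independent oracles used to cross-check the package's operations.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Ends-free alignment oracle: value DP over doubles encoding the
# lexicographic objective (score, matches, qcore, -cols). Each key lives in
# its own power-of-4096 digit so additive per-move increments preserve the
# lexicographic order; the left-move chain is resolved with a cumulative
# maximum, so the whole DP is vectorised per row.
oracle_align <- function(q, r, match = 1, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  rc <- strsplit(r, "", fixed = TRUE)[[1]]
  m <- length(qc)
  n <- length(rc)
  B <- 4096
  enc0 <- ((8000 * B + 0) * B + 0) * B + 4095 # score 0, 0 matches/qcore/cols
  d_match <- (match * B + 1) * B * B + 1 * B - 1    # +match, +1 match, +1 qcore, +1 col
  d_mismatch <- (mismatch * B + 0) * B * B + 1 * B - 1
  d_up <- (gap * B + 0) * B * B + 1 * B - 1         # query base vs gap
  d_left <- (gap * B + 0) * B * B + 0 * B - 1       # ref base vs gap
  prev <- rep(enc0, n + 1L)
  best <- enc0
  jj <- 0:n
  for (i in seq_len(m)) {
    eq <- qc[i] == rc
    diag_cand <- prev[1:n] + ifelse(eq, d_match, d_mismatch)
    up_cand <- prev[2:(n + 1L)] + d_up
    tmp <- c(enc0, pmax(diag_cand, up_cand))
    cur <- cummax(tmp - d_left * jj) + d_left * jj
    best <- max(best, cur[n + 1L])
    prev <- cur
  }
  best <- max(best, max(prev))
  dec_cols <- 4095 - best %% B
  rest <- best %/% B
  dec_qcore <- rest %% B
  rest <- rest %/% B
  dec_matches <- rest %% B
  dec_score <- rest %/% B - 8000
  list(identity = if (dec_cols > 0) 100 * dec_matches / dec_cols else 0,
       query_coverage = 100 * dec_qcore / m,
       score = dec_score, matches = dec_matches, columns = dec_cols)
}

# Greedy clustering oracle: materialise the full all-pairs identity matrix
# first, then replay the longest-first greedy assignment over it.
oracle_curate <- function(db, min_len = 1400, cluster_identity = 97) {
  db <- db[nchar(db$ssu_sequence) > min_len, , drop = FALSE]
  if (nrow(db) == 0L) return(db)
  db <- db[order(-nchar(db$ssu_sequence), db$taxon_id), , drop = FALSE]
  n <- nrow(db)
  idm <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j)
        idm[i, j] <- pairwise_identity(db$ssu_sequence[i],
                                       db$ssu_sequence[j])$identity
    }
  }
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- FALSE
    for (r in reps) if (idm[i, r] >= cluster_identity) { hit <- TRUE; break }
    if (!hit) reps <- c(reps, i)
  }
  db[reps, , drop = FALSE]
}

# N50 oracle: scan every candidate cut length.
oracle_n50 <- function(lens) {
  total <- sum(as.numeric(lens))
  cands <- sort(unique(lens), decreasing = TRUE)
  for (L in cands) {
    if (sum(as.numeric(lens[lens >= L])) >= total / 2) return(L)
  }
  min(lens)
}

# Hamming terminal-overlap oracle: try every candidate length, longest
# first, counting mismatches with a vectorised character comparison.
oracle_overlap <- function(seq, min_overlap, max_overlap, max_mismatch_frac) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- length(chars)
  hi <- min(max_overlap, len %/% 2)
  if (hi < min_overlap) return(0L)
  for (L in seq(hi, min_overlap)) {
    mm <- sum(chars[1:L] != chars[(len - L + 1):len])
    if (mm <= floor(max_mismatch_frac * L)) return(L)
  }
  0L
}

# Longest mononucleotide run, found per base with a regex.
oracle_max_run <- function(seq) {
  max(vapply(c("A", "C", "G", "T"), function(b) {
    m <- gregexpr(paste0(b, "+"), seq)[[1]]
    if (m[1] == -1) 0L else max(attr(m, "match.length"))
  }, integer(1)))
}

# Subsequence test via first-occurrence positions (valid because the
# reference arrangement has unique elements).
oracle_subseq_rotations <- function(x, reference) {
  n <- length(reference)
  for (rot in seq_len(n) - 1L) {
    r <- c(reference[(rot + 1L):n], reference[seq_len(rot)])
    for (cand in list(r, rev(r))) {
      pos <- match(x, cand)
      if (!anyNA(pos) && (length(pos) < 2L || all(diff(pos) > 0)))
        return(TRUE)
    }
  }
  FALSE
}
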