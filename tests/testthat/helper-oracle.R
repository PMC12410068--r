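# Independent reference implementation of the local alignment score,
# written as a plain-R Gotoh DP over full matrices. Used only as the oracle
# against which the package's aligner is checked; it shares no code with
# the implementation.
sw_score_oracle <- function(q, r, match = 1, mism = 1, go = 1, ge = 1) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  m <- length(qc)
  n <- length(rc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      s <- if (qc[i - 1] == rc[j - 1]) match else -mism
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
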