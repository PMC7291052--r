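# Independent oracles, deliberately naive: these re-derive expected values by
# direct enumeration and stay independent of the implementation paths they
# check.

# Count motif occurrences by an explicit loop over every window start.
naive_count_motifs <- function(sequence, motifs) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  m <- nchar(motifs[1])
  L <- nchar(s)
  if (L < m) return(0L)
  k <- 0L
  for (i in seq_len(L - m + 1L)) {
    if (substr(s, i, i + m - 1L) %in% motifs) k <- k + 1L
  }
  k
}

# Upper-tail binomial probability by direct term-wise summation.
brute_binomial_tail <- function(K, n, p) {
  if (K == 0) return(1)
  i <- K:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Recompute coverage from a per-position read-start vector by expanding
# every read interval.
naive_coverage_from_starts <- function(starts, read_length) {
  L <- length(starts)
  cov <- numeric(L)
  for (s in which(starts > 0)) {
    idx <- s:min(s + read_length - 1L, L)
    cov[idx] <- cov[idx] + starts[s]
  }
  cov
}

# An 11-nt flank with a tetrad at offsets -1..+2 (offset 0 = flank char 6).
flank_with_motif <- function(motif, background = "G") {
  paste0(strrep(background, 4), motif, strrep(background, 3))
}

# Reported probe-panel kinetic parameters (packaged table), used across tests.
reported_kinetics <- function() nd1_reported_kinetics()
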