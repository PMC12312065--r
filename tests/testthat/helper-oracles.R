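# Independent brute-force oracles used to freeze expected values.

# Global affine-gap alignment score of q vs r, iterative three-state DP
# written independently in R.  First gapped base costs open, each further
# base extend.
oracle_global_score <- function(q, r, match = 1, mismatch = -2,
                                open = -4, extend = -1) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  m <- length(qs); n <- length(rs)
  if (m == 0 && n == 0) return(0)
  M <- matrix(-Inf, m + 1, n + 1)   # last op consumes both
  D <- matrix(-Inf, m + 1, n + 1)   # gap in query (consumes r)
  I <- matrix(-Inf, m + 1, n + 1)   # gap in ref (consumes q)
  M[1, 1] <- 0
  for (j in seq_len(n) + 1)
    D[1, j] <- open + (j - 2) * extend
  for (i in seq_len(m) + 1)
    I[i, 1] <- open + (i - 2) * extend
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      s <- if (qs[i - 1] == rs[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], D[i - 1, j - 1], I[i - 1, j - 1]) + s
      D[i, j] <- max(M[i, j - 1] + open, D[i, j - 1] + extend,
                     I[i, j - 1] + open)
      I[i, j] <- max(M[i - 1, j] + open, I[i - 1, j] + extend,
                     D[i - 1, j] + open)
    }
  }
  max(M[m + 1, n + 1], D[m + 1, n + 1], I[m + 1, n + 1])
}

# Glocal score: free reference prefix/suffix = best global score of the
# query against any reference substring (including the empty one).
oracle_glocal_score <- function(q, r, ...) {
  n <- nchar(r)
  best <- -Inf
  for (a in 0:n) for (b in a:n) {
    sub <- substring(r, a + 1, b)
    s <- oracle_global_score(q, sub, ...)
    if (s > best) best <- s
  }
  best
}

# Exhaustive per-column plurality for equal-length strings.
oracle_consensus <- function(seqs, threshold = 0.6) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  apply(mat, 2, function(col) {
    tab <- sort(table(col[col %in% c("A", "C", "G", "T")]),
                decreasing = TRUE)
    if (!length(tab)) return("N")
    if (tab[1] / length(col) >= threshold) names(tab)[1] else "N"
  }) |> paste(collapse = "")
}

# Brute-force PAM scan: any NGG or CC-initial triplet whose interval lies
# within `window` nt of the position.
oracle_pam <- function(pos, seq, window = 3) {
  n <- nchar(seq)
  for (q in 0:(n - 3)) {
    d <- max(0, q - pos, pos - (q + 2))
    if (d > window) next
    tri <- substring(seq, q + 1, q + 3)
    if (substring(tri, 2, 3) == "GG" || substring(tri, 1, 2) == "CC")
      return(TRUE)
  }
  FALSE
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna_vec <- function(n, len) duplexr:::random_dna(n, len)
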