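# Independent oracles used by the tests. These deliberately re-derive
# results through different algorithms/representations than the package.

# Brute-force affine-gap local alignment score in plain R (full 3-matrix
# Gotoh DP, no optimizations). Gap of length L costs gap_open + (L-1)*ext.
sw_oracle_score <- function(q, t, match = 2, mismatch = -2, gap_open = -4,
                            gap_extend = -1) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_extend)
      s <- if (qc[i] == tc[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  max(H)
}

# AUC by direct pairwise concordance enumeration
auc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (ng in neg)
    tot <- tot + (p > ng) + 0.5 * (p == ng)
  tot / (length(pos) * length(neg))
}

# PERMANOVA pseudo-F through Gower centering (independent formulation):
# G = -0.5 * J D2 J, SS_total = tr(G), SS_among via hat matrix of the
# group-indicator design.
permanova_f_oracle <- function(d2, grp) {
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% d2 %*% J
  X <- stats::model.matrix(~factor(grp))
  Hm <- X %*% solve(crossprod(X)) %*% t(X)
  a <- length(unique(grp))
  ss_among <- sum(diag(Hm %*% G %*% Hm))
  ss_resid <- sum(diag((diag(n) - Hm) %*% G %*% (diag(n) - Hm)))
  (ss_among / (a - 1)) / (ss_resid / (n - a))
}

# exhaustive PERMANOVA p-value by direct enumeration of assignments
permanova_p_oracle <- function(d2, grp) {
  labs <- unique(grp)
  n <- length(grp)
  n1 <- sum(grp == labs[1])
  f_obs <- permanova_f_oracle(d2, grp)
  combos <- utils::combn(n, n1)
  fs <- apply(combos, 2, function(idx) {
    g <- rep(labs[2], n); g[idx] <- labs[1]
    permanova_f_oracle(d2, g)
  })
  mean(fs >= f_obs - 1e-12)
}

# J-anchor motif scan over every offset: first TTT/TTC/TGG codon whose
# translated 4-codon window reads [FW] G x G
j_anchor_oracle <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(seq)
  for (k in 0:(n - 12)) {
    aa <- sapply(0:3, function(c)
      unname(code[substr(seq, k + 3 * c + 1, k + 3 * c + 3)]))
    if (!anyNA(aa) && aa[1] %in% c("F", "W") && aa[2] == "G" && aa[4] == "G")
      return(k)
  }
  NA_integer_
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
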