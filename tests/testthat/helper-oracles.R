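# Independent scalar oracles used to cross-check the vectorized estimators.
# Deliberately written as plain transliterations of the defining formulas,
# sharing no code with the package implementation.

oracle_hudson <- function(p1, n1, p2, n2) {
  if (n1 < 2 || n2 < 2) return(NA_real_)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den <= 0) return(NA_real_)
  num / den
}

oracle_branch <- function(fst) {
  if (is.na(fst)) return(NA_real_)
  -log(1 - min(fst, 1 - 1e-12))
}

oracle_pbs <- function(pt, nt, pr, nr, po, no) {
  f_tr <- oracle_hudson(pt, nt, pr, nr)
  f_to <- oracle_hudson(pt, nt, po, no)
  f_ro <- oracle_hudson(pr, nr, po, no)
  if (anyNA(c(f_tr, f_to, f_ro))) return(NA_real_)
  (oracle_branch(f_tr) + oracle_branch(f_to) - oracle_branch(f_ro)) / 2
}

# two-sided Fisher exact p by full enumeration of tables with fixed margins;
# probabilities from exact log-factorials, not dhyper
enum_fisher_p <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c; n <- row1 + row2
  if (row1 == 0 || row2 == 0) return(NA_real_)
  lp <- function(x) {
    # P(table with top-left cell x | margins)
    lgamma(row1 + 1) - lgamma(x + 1) - lgamma(row1 - x + 1) +
      lgamma(row2 + 1) - lgamma(col1 - x + 1) - lgamma(row2 - col1 + x + 1) -
      (lgamma(n + 1) - lgamma(col1 + 1) - lgamma(n - col1 + 1))
  }
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- exp(vapply(support, lp, 0))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# hypergeometric upper tail P(X >= k) by direct summation of choose() terms
enum_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k <= max(0, K + n - N)) return(1)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# brute-force SNP-in-interval test under the BED half-open convention
brute_overlap <- function(chrom, pos, ann) {
  hits <- character()
  for (j in seq_len(nrow(ann))) {
    if (sub("^chr", "", chrom) == sub("^chr", "", ann$chrom[j]) &&
        ann$start[j] < pos && pos <= ann$end[j])
      hits <- c(hits, ann$gene[j])
  }
  unique(hits)
}
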