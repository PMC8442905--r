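# Independent oracle implementations used to check package results. These
# deliberately use different computational routes than the package code.

# Quadratic-time AUC: fraction of positive/negative pairs where the positive
# scores higher, ties counted 1/2.
brute_force_auc <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by full enumeration of the hypergeometric support,
# summing outcomes no more probable than the observed table (R's rule).
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + c           # column-1 margin
  n <- b + d           # column-2 margin
  k <- a + b           # row-1 margin
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Welch two-sample t written out from first principles.
welch_by_hand <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Kruskal-Wallis H from the rank-sum definition with explicit tie correction.
kruskal_by_hand <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Tiny deterministic call-table builder: one row per CpG.
cpg_table <- function(chrom, start, n_meth, n_unmeth) {
  data.table::data.table(chrom = chrom, start = start, end = start + 1L,
                         n_meth = n_meth, n_unmeth = n_unmeth)
}
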