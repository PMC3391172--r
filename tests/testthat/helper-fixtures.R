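# small builders shared across test files

# annotation with the first n_x genes on the X, the rest spread on autosomes
make_annot <- function(ids, n_x) {
  arms <- rep(c("2L", "2R", "3L", "3R"), length.out = length(ids))
  arms[seq_len(n_x)] <- "X"
  gene_annotation(ids, arms)
}

# a tiny tissue panel from a named signal matrix (rows = genes)
make_panel <- function(signals, calls = NULL) {
  tissue_panel(signals, calls = calls)
}

# independent Pearson correlation: textbook product-moment formula,
# written as explicit sums (no call to stats::cor)
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# independent two-sided Fisher p: enumerate every table with the observed
# margins, probabilities from binomial coefficients (lchoose), sum those
# not exceeding the observed table's probability
fisher_by_enumeration <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + b          # row-1 margin
  k <- a + c          # col-1 margin
  denom <- lchoose(N, m)
  support <- max(0, m - (N - k)):min(m, k)
  lp <- lchoose(k, support) + lchoose(N - k, m - support) - denom
  p <- exp(lp)
  p_obs <- exp(lchoose(k, a) + lchoose(N - k, m - a) - denom)
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
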