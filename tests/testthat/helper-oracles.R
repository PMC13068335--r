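# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# All-pairs Mann-Whitney AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counted half.
auc_oracle <- function(scores, labels) {
  labels <- factor(labels)
  pos <- scores[labels == levels(labels)[2]]
  neg <- scores[labels == levels(labels)[1]]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# O(N*m) running-sum enrichment score: explicit walk down the sorted list.
es_oracle <- function(scores, gene_set, alpha = 1) {
  ord <- order(-scores, names(scores), method = "radix")
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  m <- sum(hit)
  N <- length(s)
  if (m == 0) return(NA_real_)
  denom <- sum(abs(s[hit])^alpha)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (denom > 0) abs(s[i])^alpha / denom else 1 / m
    } else -1 / (N - m)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Step-up BH from the definition: q_(i) = min over j >= i of p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Hypergeometric upper tail by direct enumeration of the density.
fisher_oracle <- function(overlap, set_size, universe_size, list_size) {
  kmax <- min(set_size, list_size)
  sum(vapply(overlap:kmax, function(k)
    choose(set_size, k) * choose(universe_size - set_size, list_size - k) /
      choose(universe_size, list_size), numeric(1)))
}

# Group-by mean via an explicit loop.
groupby_mean_oracle <- function(values, groups) {
  out <- matrix(NA_real_, length(unique(groups)), ncol(values),
                dimnames = list(unique(groups), colnames(values)))
  for (g in unique(groups))
    out[g, ] <- colMeans(values[groups == g, , drop = FALSE])
  out
}
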