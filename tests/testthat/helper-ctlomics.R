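# Shared fixtures and independent oracles used across the test files.

# small labeled log2 matrix with optional planted shift in the "high" group
make_labeled_matrix <- function(n_genes, n_high, n_low, shift_genes = integer(),
                                shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- n_high + n_low
  m <- matrix(rnorm(n_genes * n, sd = sd), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  if (length(shift_genes)) m[shift_genes, seq_len(n_high)] <-
      m[shift_genes, seq_len(n_high)] + shift
  labels <- tibble::tibble(
    sample_id = colnames(m),
    label = factor(rep(c("high", "low"), c(n_high, n_low)),
                   levels = c("high", "low", "unclassified")))
  list(mat = m, labels = labels)
}

# all-pairs concordance AUC with ties counted 1/2
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# direct per-position running-sum GSEA oracle (independent loop, no cumsum)
oracle_es <- function(features, weights, gene_set, exponent = 1) {
  ord <- order(weights, decreasing = TRUE)
  f <- features[ord]; w <- weights[ord]
  hit <- f %in% gene_set
  nr <- sum(abs(w[hit])^exponent)
  running <- numeric(length(f))
  acc <- 0
  for (i in seq_along(f)) {
    acc <- if (hit[i]) acc + abs(w[i])^exponent / nr else
      acc - 1 / (length(f) - sum(hit))
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# exact null distribution of TF-in-subset counts by full enumeration
oracle_enrichment_p <- function(network_size, tf_set, universe, observed) {
  subsets <- utils::combn(length(universe), network_size)
  counts <- apply(subsets, 2, function(i) length(intersect(universe[i], tf_set)))
  mean(counts >= observed)
}

# Welch t per feature via stats::t.test (independent of welch_rows)
oracle_welch <- function(mat, idx1, idx2) {
  t(apply(mat, 1, function(v) {
    tt <- t.test(v[idx1], v[idx2])
    c(t = unname(tt$statistic), p = tt$p.value,
      fc = mean(v[idx1]) - mean(v[idx2]))
  }))
}
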