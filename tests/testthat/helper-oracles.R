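# Independent oracles and shared fixtures. Oracles are deliberately naive
# (brute force, enumeration, closed form) and never call the code paths
# they check.

# Pairwise-concordance AUC: loop over every positive-negative pair,
# ties count one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up: p * m / rank with a running minimum from the
# largest p down, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Exact hypergeometric upper tail P(X >= k) by term enumeration.
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small cohort configuration reused by tests that only need structure, not
# power.
small_cfg <- function(...) {
  sim_config(n_patients = 30, n_probes = 120, n_genes = 60,
             n_predictive_probes = 10, n_bicluster_probes = 15,
             n_bicluster_genes = 10, ...)
}

# Adjusted Rand index between a bicluster_set and the planted membership,
# for a given feature type.
planted_ari <- function(bc, truth, type) {
  m <- merge(bc$assignments, truth$bicluster_membership, by = c("feature", "type"))
  m <- m[m$type == type, ]
  mclust::adjustedRandIndex(m$bicluster.x, m$bicluster.y)
}

# Beta matrix helper with probe/sample names.
beta_mat <- function(values, nrow, probes = sprintf("cg%02d", seq_len(nrow)),
                     samples = sprintf("s%02d", seq_len(length(values) / nrow))) {
  matrix(values, nrow = nrow, dimnames = list(probes, samples))
}

# Construct meth/expr matrices realizing exact target correlations: probe
# vectors are orthonormal (and orthogonal to the constant vector), each
# gene is rho * own-probe + sqrt(1 - rho^2) * an orthogonal residual, so
# cor(probe_j, gene_j) == rho_j exactly and all cross-correlations are 0.
exact_corr_design <- function(probes, rhos, n_samples = 30, seed = 1) {
  k <- length(probes)
  stopifnot(2 * k + 1 <= n_samples)
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n_samples * 2 * k), n_samples))))[, -1]
  x <- q[, seq_len(k), drop = FALSE]
  e <- q[, k + seq_len(k), drop = FALSE]
  meth <- t(0.5 + 0.15 * scale(x))  # affine map into [0,1]; correlations unchanged
  rownames(meth) <- probes
  colnames(meth) <- sprintf("s%02d", seq_len(n_samples))
  genes <- t(vapply(seq_len(k), function(j) {
    rhos[j] * x[, j] + sqrt(1 - rhos[j]^2) * e[, j]
  }, numeric(n_samples)))
  rownames(genes) <- paste0("gene_", probes)
  colnames(genes) <- colnames(meth)
  list(meth = meth, expr = genes)
}

# Path of the published 11-CpG signature shipped with the package.
published_signature_path <- function() {
  system.file("extdata", "bev_response_signature.tsv", package = "methrx")
}
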