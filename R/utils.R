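# Internal validators and small helpers shared across modules.

# Stop with a classed error so tests can target methrx failures specifically.
stop_methrx <- function(msg, class = "methrx_error") {
  rlang::abort(msg, class = class)
}

# Validate a probe/gene x sample matrix. `kind` switches the value checks:
# beta values must lie in [0, 1]; expression values only need to be finite.
validate_matrix <- function(m, kind = c("beta", "expr"), what = "matrix") {
  kind <- match.arg(kind)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_methrx(sprintf("%s must be a numeric matrix", what))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_methrx(sprintf("%s must have row (feature) and column (sample) names", what))
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    stop_methrx(sprintf("duplicate feature ids in %s: %s", what,
                        paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    stop_methrx(sprintf("duplicate sample ids in %s: %s", what,
                        paste(head(dup, 5), collapse = ", ")))
  }
  vals <- m[!is.na(m)]
  if (kind == "beta") {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      i <- bad[1, 1]; j <- bad[1, 2]
      stop_methrx(sprintf(
        "beta value out of [0,1] in %s: probe '%s', sample '%s' (value %g)%s",
        what, rownames(m)[i], colnames(m)[j], m[i, j],
        if (nrow(bad) > 1) sprintf(" and %d more", nrow(bad) - 1) else ""),
        class = "methrx_invalid_beta")
    }
  } else if (length(vals) && any(!is.finite(vals))) {
    stop_methrx(sprintf("non-finite values in %s", what))
  }
  invisible(m)
}

# Align two matrices on their shared samples (columns), order-normalized.
shared_samples <- function(a, b, min_n = 1L) {
  common <- intersect(colnames(a), colnames(b))
  if (length(common) < min_n) {
    stop_methrx(sprintf("only %d shared sample(s); need at least %d",
                        length(common), min_n))
  }
  sort(common)
}

# Fraction-based concordance is used in several places; keep a single
# rank-based AUC helper (ties count 1/2) with an exact tie correction.
auc_rank <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_methrx("both classes required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Standardize to mean 0, sd 1.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop_methrx("cannot standardize a zero-variance vector")
  (x - mean(x)) / s
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
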