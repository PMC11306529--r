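# Delta emQTL analysis: all-pairs correlation between treatment-induced
# methylation changes and expression changes, Bonferroni screening, and
# spectral co-clustering of the CpG-gene correlation structure into
# biclusters whose average delta methylation is then tested against
# response.
#
# The co-clustering is the bipartite spectral algorithm: normalize the
# non-negative affinity matrix A as D1^(-1/2) A D2^(-1/2), take the leading
# 1 + ceil(log2(k)) singular vector pairs (dropping the trivial first one),
# stack the degree-scaled row and column embeddings, and k-means the joint
# embedding into k groups so every CpG and gene lands in exactly one
# bicluster. Because within-bicluster CpG-gene delta correlations are
# negative, the affinity is the negated Pearson correlation floored at zero
# (configurable).

#' Per-patient delta matrix between two timepoints
#'
#' @param t0,t1 Feature-by-sample matrices at the earlier and later
#'   timepoint.
#' @param annot Cohort annotation mapping `sample_id` to `patient_id`.
#' @return A feature-by-patient matrix of `t1 - t0` differences, columns
#'   named by patient; patients lacking either timepoint are dropped with a
#'   message.
#' @export
paired_delta <- function(t0, t1, annot) {
  features <- intersect(rownames(t0), rownames(t1))
  if (length(features) == 0) stop_methrx("no shared features between matrices")
  pair <- build_pairs(annot, colnames(t0), colnames(t1))
  if (nrow(pair) == 0) stop_methrx("no patient has samples at both timepoints")
  d <- t1[features, pair$after, drop = FALSE] - t0[features, pair$before, drop = FALSE]
  colnames(d) <- pair$patient
  d[, order(colnames(d)), drop = FALSE]
}

#' All-pairs delta methylation / delta expression correlation scan
#'
#' Computes the Pearson correlation and two-sided p-value for every
#' CpG-gene pair of per-patient deltas, Bonferroni-corrects over the number
#' of tested pairs, and flags pairs with corrected p strictly below
#' `alpha`. Features that are constant across patients are not tested.
#'
#' @param dm Probe-by-patient delta methylation matrix.
#' @param de Gene-by-patient delta expression matrix (>= 4 shared patients).
#' @param alpha Familywise significance level on the Bonferroni-corrected p.
#' @return A tibble with `probe`, `gene`, `r`, `p`, `p_bonf`, `significant`;
#'   attributes `n_patients` and `n_tested_pairs`.
#' @export
emqtl_scan <- function(dm, de, alpha = 0.05) {
  common <- shared_samples(dm, de, min_n = 4L)
  if (length(common) < 4) stop_methrx("need at least 4 shared patients")
  x <- dm[, common, drop = FALSE]
  y <- de[, common, drop = FALSE]
  x <- x[apply(x, 1, sd) > 0, , drop = FALSE]
  y <- y[apply(y, 1, sd) > 0, , drop = FALSE]
  if (nrow(x) == 0 || nrow(y) == 0) stop_methrx("no non-constant features to test")
  n <- length(common)
  r <- cor(t(x), t(y))
  df <- n - 2
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  m <- length(r)
  out <- tibble::tibble(
    probe = rep(rownames(x), times = ncol(r)),
    gene = rep(colnames(r), each = nrow(r)),
    r = as.numeric(r), p = as.numeric(p),
    p_bonf = pmin(1, as.numeric(p) * m))
  out$significant <- out$p_bonf < alpha
  attr(out, "n_patients") <- n
  attr(out, "n_tested_pairs") <- m
  out
}

# Assemble the probe x gene correlation matrix over features with at least
# one significant association (all retained cells, not only significant
# ones).
assoc_matrix <- function(assoc) {
  keep_p <- unique(assoc$probe[assoc$significant])
  keep_g <- unique(assoc$gene[assoc$significant])
  if (length(keep_p) == 0 || length(keep_g) == 0) {
    stop_methrx("no feature has a significant association")
  }
  sub <- assoc[assoc$probe %in% keep_p & assoc$gene %in% keep_g, ]
  m <- matrix(0, length(keep_p), length(keep_g), dimnames = list(keep_p, keep_g))
  m[cbind(match(sub$probe, keep_p), match(sub$gene, keep_g))] <- sub$r
  m
}

# Bipartite spectral embedding of a non-negative affinity matrix.
spectral_embedding <- function(a, k) {
  a <- a + 1e-12  # guard all-zero rows/columns
  d1 <- 1 / sqrt(rowSums(a))
  d2 <- 1 / sqrt(colSums(a))
  an <- a * outer(d1, d2)
  n_sv <- 1 + ceiling(log2(k))
  sv <- svd(an, nu = min(n_sv, ncol(an)), nv = min(n_sv, ncol(an)))
  idx <- 2:min(n_sv, length(sv$d))
  z_rows <- d1 * sv$u[, idx, drop = FALSE]
  z_cols <- d2 * sv$v[, idx, drop = FALSE]
  list(rows = z_rows, cols = z_cols)
}

#' Spectral co-clustering of delta emQTL correlation structure
#'
#' Partitions the CpGs and genes carrying at least one significant
#' association into `k` joint biclusters (each feature in exactly one).
#'
#' @param assoc An [emqtl_scan()] result.
#' @param k Number of biclusters.
#' @param seed Seed for the k-means step.
#' @param transform How to turn correlations into non-negative affinities:
#'   `"neg_floor"` (default) uses `max(-r, 0)` so negative CpG-gene
#'   correlations become positive affinity; `"abs"` uses `|r|`.
#' @return An object of class `bicluster_set`: list with `assignments`
#'   (tibble: `feature`, `type`, `bicluster`), `k`, the affinity matrix and
#'   the spectral embedding.
#' @export
cocluster <- function(assoc, k, seed = 0, transform = c("neg_floor", "abs")) {
  transform <- match.arg(transform)
  r <- assoc_matrix(assoc)
  if (k < 1) stop_methrx("k must be >= 1")
  if (k > min(dim(r))) {
    stop_methrx(sprintf("k = %d exceeds min(#probes, #genes) = %d", k, min(dim(r))))
  }
  a <- switch(transform, neg_floor = pmax(-r, 0), abs = abs(r))
  if (k == 1) {
    assignments <- tibble::tibble(
      feature = c(rownames(r), colnames(r)),
      type = c(rep("probe", nrow(r)), rep("gene", ncol(r))),
      bicluster = 1L)
    return(structure(list(assignments = assignments, k = 1L, affinity = a,
                          embedding = NULL),
                     class = "bicluster_set"))
  }
  emb <- spectral_embedding(a, k)
  z <- rbind(emb$rows, emb$cols)
  if (nrow(unique(z)) < k) stop_methrx("degenerate matrix: fewer distinct embedding points than k")
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = 25, iter.max = 100)
  cl <- km$cluster
  # Deterministic labels: renumber clusters by order of first appearance.
  relabel <- match(cl, unique(cl))
  assignments <- tibble::tibble(
    feature = c(rownames(r), colnames(r)),
    type = c(rep("probe", nrow(r)), rep("gene", ncol(r))),
    bicluster = relabel)
  structure(list(assignments = assignments, k = as.integer(k), affinity = a,
                 embedding = z, withinss = km$tot.withinss),
            class = "bicluster_set")
}

#' @export
print.bicluster_set <- function(x, ...) {
  tab <- table(x$assignments$bicluster, x$assignments$type)
  cat(sprintf("bicluster_set: k = %d\n", x$k))
  print(tab)
  invisible(x)
}

#' Select the number of biclusters by silhouette score
#'
#' Runs [cocluster()] for every `k` in `k_range` and scores each partition
#' by the mean silhouette width of the joint spectral embedding (Euclidean
#' distance). Returns the maximizing `k` together with the full score table.
#'
#' @inheritParams cocluster
#' @param k_range Candidate numbers of biclusters (values exceeding the
#'   matrix dimensions are skipped).
#' @return A list with `k` (the maximizer) and `scores` (tibble of `k` and
#'   mean `silhouette`).
#' @export
select_k <- function(assoc, k_range = 2:8, seed = 0,
                     transform = c("neg_floor", "abs")) {
  transform <- match.arg(transform)
  r <- assoc_matrix(assoc)
  if (max(abs(r - mean(r))) < 1e-15) stop_methrx("degenerate (all-equal) correlation matrix")
  k_range <- k_range[k_range >= 2 & k_range <= min(dim(r))]
  if (length(k_range) == 0) stop_methrx("no feasible k in k_range")
  scores <- vapply(k_range, function(k) {
    bc <- cocluster(assoc, k, seed = seed, transform = transform)
    sil <- cluster::silhouette(bc$assignments$bicluster, stats::dist(bc$embedding))
    mean(sil[, "sil_width"])
  }, numeric(1))
  tab <- tibble::tibble(k = as.integer(k_range), silhouette = scores)
  list(k = tab$k[which.max(tab$silhouette)], scores = tab)
}

#' Average per-patient delta over a bicluster's features
#'
#' @param dm Feature-by-patient delta matrix (methylation or expression).
#' @param bc A [cocluster()] result.
#' @param bicluster Which bicluster to score.
#' @param type Feature type to average (`"probe"` for delta methylation,
#'   `"gene"` for delta expression).
#' @return A tibble with `patient_id` and `score` (the arithmetic mean of
#'   the bicluster's feature deltas).
#' @export
bicluster_delta_score <- function(dm, bc, bicluster = 1, type = c("probe", "gene")) {
  type <- match.arg(type)
  stopifnot(inherits(bc, "bicluster_set"))
  feats <- bc$assignments$feature[bc$assignments$bicluster == bicluster &
                                    bc$assignments$type == type]
  if (length(feats) == 0) stop_methrx(sprintf("bicluster %s has no %s features", bicluster, type))
  missing_f <- setdiff(feats, rownames(dm))
  if (length(missing_f)) {
    stop_methrx(paste0("feature(s) absent from delta matrix: ",
                       paste(head(missing_f, 10), collapse = ", ")))
  }
  tibble::tibble(patient_id = colnames(dm),
                 score = unname(colMeans(dm[feats, , drop = FALSE])))
}

#' Associate a per-patient score with treatment response
#'
#' Dichotomous endpoints (`pcr`, `rcb`) are compared by a two-sided
#' two-sample t-test; the continuous endpoint (`fraction` of tumor left) by
#' a Pearson correlation test.
#'
#' @param score Tibble with `patient_id` and `score` (e.g. from
#'   [bicluster_delta_score()]) or a named numeric vector.
#' @param annot Cohort annotation (patient-level fields are taken from each
#'   patient's first row).
#' @param mode `"pcr"`, `"rcb"` or `"fraction"`.
#' @param arm Optional treatment arm filter (`"combination"` or `"chemo"`).
#' @return A one-row tibble: `mode`, `arm`, `n`, `estimate` (group mean
#'   difference or correlation), `statistic`, `p`.
#' @export
associate_response <- function(score, annot, mode = c("pcr", "rcb", "fraction"),
                               arm = NULL) {
  mode <- match.arg(mode)
  if (is.numeric(score) && !is.null(names(score))) {
    score <- tibble::tibble(patient_id = names(score), score = unname(score))
  }
  pat <- annot |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::select("patient_id", "arm", "pcr", "rcb_class", "tumor_fraction_left")
  df <- dplyr::inner_join(score, pat, by = "patient_id")
  if (!is.null(arm)) df <- df[df$arm == arm, ]
  if (mode == "pcr") {
    df <- df[!is.na(df$pcr), ]
    g <- df$pcr
    check_groups(g, min_per_group = 3)
    tt <- t.test(df$score[g], df$score[!g])
    est <- mean(df$score[g]) - mean(df$score[!g])
    out <- tibble::tibble(estimate = est, statistic = unname(tt$statistic), p = tt$p.value)
  } else if (mode == "rcb") {
    df <- df[!is.na(df$rcb_class), ]
    g <- df$rcb_class == "low"
    check_groups(g, min_per_group = 3)
    tt <- t.test(df$score[g], df$score[!g])
    est <- mean(df$score[g]) - mean(df$score[!g])
    out <- tibble::tibble(estimate = est, statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    df <- df[!is.na(df$tumor_fraction_left), ]
    if (nrow(df) < 4) stop_methrx("need at least 4 patients for the correlation test")
    ct <- cor.test(df$score, df$tumor_fraction_left)
    out <- tibble::tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
                          p = ct$p.value)
  }
  dplyr::bind_cols(tibble::tibble(mode = mode, arm = arm %||% "all", n = nrow(df)), out)
}

check_groups <- function(g, min_per_group) {
  if (sum(g) == 0 || sum(!g) == 0) stop_methrx("a response group is empty")
  if (min(sum(g), sum(!g)) < min_per_group) {
    stop_methrx(sprintf("need at least %d patients per group", min_per_group))
  }
}
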