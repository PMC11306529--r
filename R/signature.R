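# Discovery, aggregation, scoring and translation of sparse predictive
# methylation signatures, plus hybrid score fusion and ROC evaluation.
#
# The discovery scheme is leave-one-out (LOO): an L1-penalized logistic
# model is fitted on the n - 1 remaining samples with the penalty chosen by
# an inner 5-fold cross-validation (minimum CV deviance over a 100-point
# log-spaced grid), and the held-out sample's response probability is
# recorded. The n per-fold models are then aggregated into one stable
# signature by keeping CpGs selected in at least half of the models and
# averaging their coefficients.

#' Leave-one-out penalized logistic signature discovery
#'
#' Fits one L1-penalized logistic regression per sample, trained on the
#' remaining samples with the penalty selected by nested k-fold
#' cross-validation (deviance-minimizing lambda), and records the held-out
#' sample's predicted response probability. Features are standardized to
#' unit variance inside the fit; reported coefficients are on the original
#' beta scale.
#'
#' @param x Probe-by-sample beta matrix, already restricted to the
#'   preselected probe list (e.g. emQTL CpGs, or a planted probe list).
#' @param y Response labels: a logical/0-1 vector named by sample, or
#'   unnamed in `colnames(x)` order.
#' @param inner_folds Folds of the inner cross-validation (default 5).
#' @param seed Integer seed controlling inner fold assignment.
#' @param standardize Standardize features inside glmnet (default `TRUE`).
#' @return An object of class `loo_signature_fit`: a list with `models`
#'   (tibble: `held_out`, `probe`, `coef`), `intercepts`, `lambdas`, and
#'   `loo` (tibble: `sample_id`, `y`, `probability`).
#' @export
loo_lasso <- function(x, y, inner_folds = 5, seed = 0, standardize = TRUE) {
  validate_matrix(x, kind = "beta", what = "beta matrix")
  samples <- colnames(x)
  if (!is.null(names(y))) {
    missing_y <- setdiff(samples, names(y))
    if (length(missing_y)) {
      stop_methrx(paste0("labels missing for sample(s): ", paste(head(missing_y, 5), collapse = ", ")))
    }
    y <- y[samples]
  }
  y <- as.numeric(y)
  n <- length(samples)
  if (length(y) != n) stop_methrx("length(y) must match the number of samples")
  if (anyNA(y)) stop_methrx("missing response labels are not allowed")
  if (length(unique(y)) < 2) stop_methrx("response has a single class; two classes required")
  if (min(table(y)) < 2) stop_methrx("need at least 2 samples per class")
  if (n < inner_folds + 1) {
    stop_methrx(sprintf("need more than inner_folds (%d) samples; got %d", inner_folds, n))
  }
  if (anyNA(x)) stop_methrx("missing beta values are not allowed in loo_lasso; impute or drop first")

  xt <- t(x)
  set.seed(seed)
  fits <- vector("list", n)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    xi <- xt[-i, , drop = FALSE]
    yi <- y[-i]
    foldid <- stratified_folds(yi, inner_folds)
    constant <- all(apply(xi, 2, function(v) diff(range(v)) == 0))
    if (constant) {
      # No usable variance anywhere: intercept-only model.
      b0 <- qlogis(mean(yi))
      fits[[i]] <- list(coefs = numeric(0), probes = character(0),
                        intercept = b0, lambda = Inf)
      probs[i] <- plogis(b0)
      next
    }
    # glmnet nags when a class has < 8 observations per fold; expected at
    # leave-one-out scale and harmless for penalty selection
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(xi, yi, family = "binomial", alpha = 1,
                        nfolds = inner_folds, foldid = foldid,
                        nlambda = 100, standardize = standardize,
                        type.measure = "deviance"),
      warning = function(w) {
        msg <- conditionMessage(w)
        # also muffle path truncation at the smallest penalties: glmnet
        # returns the converged prefix, which is all penalty selection needs
        if (grepl("fewer than 8\\s+observations|lambda value not reached", msg)) {
          invokeRestart("muffleWarning")
        }
      })
    cf <- as.matrix(coef(cv, s = "lambda.min"))
    nz <- which(cf[-1, 1] != 0)
    fits[[i]] <- list(coefs = cf[-1, 1][nz], probes = rownames(cf)[-1][nz],
                      intercept = cf[1, 1], lambda = cv$lambda.min)
    probs[i] <- as.numeric(predict(cv, newx = xt[i, , drop = FALSE],
                                   s = "lambda.min", type = "response"))
  }

  models <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    if (length(fits[[i]]$probes) == 0) return(NULL)
    tibble::tibble(held_out = samples[i], probe = fits[[i]]$probes,
                   coef = unname(fits[[i]]$coefs))
  }))
  if (nrow(models) == 0) {
    models <- tibble::tibble(held_out = character(), probe = character(), coef = numeric())
  }
  structure(list(
    models = models,
    intercepts = setNames(vapply(fits, `[[`, numeric(1), "intercept"), samples),
    lambdas = setNames(vapply(fits, `[[`, numeric(1), "lambda"), samples),
    loo = tibble::tibble(sample_id = samples, y = y == max(y), probability = probs),
    n_models = n, seed = seed
  ), class = "loo_signature_fit")
}

# Stratified fold assignment: shuffle within each class, then deal folds
# round-robin so every fold sees both classes whenever possible.
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

#' Aggregate leave-one-out models into a stable signature
#'
#' Keeps the CpGs selected (nonzero) in at least `min_freq` of the models
#' (inclusive threshold) and averages their coefficients; the intercept is
#' the mean over all models. Coefficient averaging is over the models where
#' the probe is present (default) or over all models counting absence as
#' zero (`coef_average = "all"`).
#'
#' @param fit A [loo_lasso()] fit.
#' @param min_freq Minimum fraction of models a probe must appear in.
#' @param coef_average `"present"` or `"all"` (see above).
#' @return A [meth_signature()] tibble with columns `probe`, `coef`,
#'   `n_models`, `freq`; the averaging rule is stored in the
#'   `coef_average` attribute. A signature with zero probes is returned
#'   with a warning when no probe reaches `min_freq`.
#' @export
aggregate_signature <- function(fit, min_freq = 0.5,
                                coef_average = c("present", "all")) {
  stopifnot(inherits(fit, "loo_signature_fit"))
  coef_average <- match.arg(coef_average)
  n <- fit$n_models
  if (n == 0) stop_methrx("empty model set")
  tab <- fit$models |>
    dplyr::group_by(.data$probe) |>
    dplyr::summarise(n_models = dplyr::n(), sum_coef = sum(.data$coef),
                     .groups = "drop") |>
    dplyr::mutate(freq = .data$n_models / n,
                  coef = if (coef_average == "present") .data$sum_coef / .data$n_models
                         else .data$sum_coef / n) |>
    dplyr::filter(.data$freq >= min_freq) |>
    dplyr::arrange(dplyr::desc(abs(.data$coef)))
  if (nrow(tab) == 0) {
    rlang::warn("no probe reached min_freq; returning an empty signature")
  }
  sig <- meth_signature(probe = tab$probe, coef = tab$coef,
                        intercept = mean(fit$intercepts))
  sig$n_models <- tab$n_models
  sig$freq <- tab$freq
  attr(sig, "coef_average") <- coef_average
  sig
}

#' Score samples with a signature
#'
#' The score of a sample is the model intercept plus the sum over signature
#' features of coefficient times measured value; the response probability is
#' the logistic transform of the score.
#'
#' @param sig A `meth_signature` (applied to a beta matrix) or
#'   `expr_signature` (applied to an expression matrix).
#' @param m Feature-by-sample matrix containing every signature feature.
#' @return A tibble with `sample_id`, `score` and `probability`.
#' @export
score_samples <- function(sig, m) {
  feature_col <- if (inherits(sig, "meth_signature")) "probe" else "gene"
  features <- sig[[feature_col]]
  missing_f <- setdiff(features, rownames(m))
  if (length(missing_f)) {
    stop_methrx(paste0("signature feature(s) absent from matrix: ",
                       paste(missing_f, collapse = ", ")))
  }
  sub <- m[features, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(is.na(sub), arr.ind = TRUE)[1, ]
    stop_methrx(sprintf("missing value for signature feature '%s' in sample '%s'",
                        rownames(sub)[bad[1]], colnames(sub)[bad[2]]))
  }
  score <- sig_intercept(sig) + as.numeric(crossprod(sub, sig$coef))
  tibble::tibble(sample_id = colnames(m), score = score,
                 probability = plogis(score))
}

#' Translate a methylation signature into an expression signature
#'
#' For each signature CpG, finds the gene whose expression has the highest
#' absolute Pearson correlation with the CpG's methylation across the shared
#' samples, and multiplies the CpG coefficient by that (signed) correlation.
#' Exact |r| ties break to the lexicographically smaller gene id.
#'
#' @param sig A `meth_signature`.
#' @param meth Probe-by-sample beta matrix covering the signature probes.
#' @param expr Gene-by-sample expression matrix sharing >= 3 samples with
#'   `meth`.
#' @return An [expr_signature()] with provenance columns `probe` and `rho`.
#'   Probes with zero methylation variance are skipped with a warning.
#' @export
translate_signature <- function(sig, meth, expr) {
  stopifnot(inherits(sig, "meth_signature"))
  common <- shared_samples(meth, expr, min_n = 3L)
  missing_f <- setdiff(sig$probe, rownames(meth))
  if (length(missing_f)) {
    stop_methrx(paste0("signature probe(s) absent from methylation matrix: ",
                       paste(missing_f, collapse = ", ")))
  }
  mm <- meth[sig$probe, common, drop = FALSE]
  ee <- expr[, common, drop = FALSE]
  keep_genes <- apply(ee, 1, sd) > 0
  ee <- ee[keep_genes, , drop = FALSE]
  if (nrow(ee) == 0) stop_methrx("no expression variance in shared samples")

  rows <- lapply(seq_len(nrow(mm)), function(i) {
    v <- mm[i, ]
    if (sd(v) == 0) return(NULL)
    r <- as.numeric(cor(v, t(ee)))
    best <- abs(r) == max(abs(r))
    gene <- sort(rownames(ee)[best])[1]
    tibble::tibble(probe = sig$probe[i], gene = gene,
                   rho = r[match(gene, rownames(ee))])
  })
  skipped <- sig$probe[vapply(rows, is.null, logical(1))]
  if (length(skipped)) {
    rlang::warn(paste0("skipping zero-variance probe(s): ", paste(skipped, collapse = ", ")))
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) stop_methrx("no translatable probes")
  coefs <- sig$coef[match(tab$probe, sig$probe)]
  expr_signature(gene = tab$gene, coef = coefs * tab$rho,
                 intercept = sig_intercept(sig), probe = tab$probe, rho = tab$rho)
}

#' Average two scores on a standardized scale
#'
#' Each score vector is standardized to mean 0 and standard deviation 1, and
#' the per-sample average of the two standardized vectors is returned.
#'
#' @param a,b Numeric score vectors over the same samples (named, or tibbles
#'   from [score_samples()] with `sample_id` and `score` columns).
#' @return A tibble with `sample_id` and `hybrid`.
#' @export
hybrid_score <- function(a, b) {
  as_scores <- function(x, what) {
    if (is.data.frame(x)) {
      if (!all(c("sample_id", "score") %in% names(x))) {
        stop_methrx(sprintf("%s must have sample_id and score columns", what))
      }
      setNames(x$score, x$sample_id)
    } else if (is.numeric(x)) {
      if (is.null(names(x))) setNames(x, paste0("s", seq_along(x))) else x
    } else stop_methrx(sprintf("%s must be numeric or a score tibble", what))
  }
  va <- as_scores(a, "a"); vb <- as_scores(b, "b")
  if (length(va) != length(vb) || !setequal(names(va), names(vb))) {
    stop_methrx("a and b must cover the same samples")
  }
  vb <- vb[names(va)]
  tibble::tibble(sample_id = names(va),
                 hybrid = unname((zscore(va) + zscore(vb)) / 2))
}

#' ROC curve, AUC and optimal cutoff
#'
#' The AUC is the pairwise concordance fraction over all positive-negative
#' pairs with ties counting one half. The optimal cutoff maximizes Youden's
#' J = sensitivity + specificity - 1; exact J ties break toward the cutoff
#' with higher specificity. Samples scoring at or above the cutoff are
#' called positive.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical/0-1 class labels, same length.
#' @return An object of class `roc_result`: list with `auc`, `curve`
#'   (tibble of cutoffs with sensitivity and specificity), `optimal_cutoff`,
#'   `sensitivity` and `specificity` at the optimum.
#' @export
roc_with_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop_methrx("scores and labels must be complete and of equal length")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_methrx("both classes must be present")
  auc <- auc_rank(scores, labels)

  cutoffs <- sort(unique(scores))
  curve <- tibble::tibble(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(c) sum(labels & scores >= c) / n_pos, numeric(1)),
    specificity = vapply(cutoffs, function(c) sum(!labels & scores < c) / n_neg, numeric(1))
  )
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(curve$specificity[best])]
  structure(list(auc = auc, curve = curve,
                 optimal_cutoff = curve$cutoff[best],
                 sensitivity = curve$sensitivity[best],
                 specificity = curve$specificity[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d pos / %d neg)\n", x$auc, x$n_pos, x$n_neg))
  cat(sprintf("optimal cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$optimal_cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
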