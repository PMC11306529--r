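# Cancer-cell-specific methylation estimation. Bulk beta values mix tumor
# and non-tumor methylation in proportion to tumor purity. Under the
# assumption that the non-tumor methylation level of each CpG is constant
# across samples, regressing beta on purity per CpG and extrapolating the
# fitted line to purity 1, then adding back each sample's residual,
# recovers the tumor-cell methylation:
#   corrected_ij = (a_j + b_j) + (m_ij - a_j - b_j p_i) = m_ij + b_j (1 - p_i).

#' Fit per-CpG linear models of beta on tumor purity
#'
#' Ordinary least squares per probe over samples with non-missing beta and
#' purity (complete-case per probe, no imputation). Probes with fewer than 3
#' usable samples or no purity variance among them are flagged unfitted.
#'
#' @param m Probe-by-sample beta matrix.
#' @param purity Tumor purity per sample, named by sample id (values in
#'   (0, 1\]); samples absent from `purity` or with missing purity are
#'   ignored in the fit.
#' @return A tibble of class `purity_fit` with `probe`, `intercept`,
#'   `slope`, `n` and `fitted` (logical).
#' @export
fit_purity_model <- function(m, purity) {
  validate_matrix(m, "beta", "beta matrix")
  if (is.null(names(purity))) stop_methrx("purity must be named by sample id")
  p <- purity[colnames(m)]
  names(p) <- colnames(m)
  usable <- !is.na(p)
  if (sum(usable) < 3) stop_methrx("need at least 3 samples with purity")
  if (sd(p[usable]) == 0) stop_methrx("purity is constant; per-CpG regression is unidentifiable")

  fit_one <- function(beta) {
    ok <- usable & !is.na(beta)
    n <- sum(ok)
    if (n < 3 || sd(p[ok]) == 0) {
      return(c(NA_real_, NA_real_, n, 0))
    }
    pp <- p[ok]; bb <- beta[ok]
    b <- cov(bb, pp) / var(pp)
    a <- mean(bb) - b * mean(pp)
    c(a, b, n, 1)
  }
  res <- t(apply(m, 1, fit_one))
  out <- tibble::tibble(probe = rownames(m),
                        intercept = unname(res[, 1]), slope = unname(res[, 2]),
                        n = as.integer(res[, 3]), fitted = res[, 4] == 1)
  class(out) <- c("purity_fit", class(out))
  out
}

#' Purity-correct a beta matrix to cancer-cell-specific methylation
#'
#' Applies `corrected = m + slope * (1 - purity)` per probe and sample: the
#' regression line's value at purity 1 (the mean tumor-cell methylation)
#' plus the sample's residual. Corrected values are clipped to \[0, 1\] and
#' the clip count reported. Unfitted probes pass through unchanged; samples
#' without purity are dropped from the output.
#'
#' @param m Probe-by-sample beta matrix (same probes as `model`).
#' @param purity Tumor purity per sample, named by sample id.
#' @param model A [fit_purity_model()] result for the same probes.
#' @return A corrected beta matrix with attributes `n_clipped` (values
#'   clipped to \[0, 1\]), `dropped_samples` and `unfitted_probes`.
#' @export
purity_correct <- function(m, purity, model) {
  stopifnot(inherits(model, "purity_fit"))
  missing_p <- setdiff(rownames(m), model$probe)
  if (length(missing_p)) {
    stop_methrx(paste0("model missing probe(s): ", paste(head(missing_p, 5), collapse = ", ")))
  }
  p <- purity[colnames(m)]
  has_p <- !is.na(p)
  dropped <- colnames(m)[!has_p]
  if (length(dropped)) {
    rlang::inform(paste0("purity_correct: dropping ", length(dropped),
                         " sample(s) without purity: ",
                         paste(head(dropped, 5), collapse = ", ")))
  }
  mm <- m[, has_p, drop = FALSE]
  p <- p[has_p]
  slope <- model$slope[match(rownames(mm), model$probe)]
  fitted <- model$fitted[match(rownames(mm), model$probe)]
  slope[!fitted] <- 0  # unfitted probes pass through unchanged
  corrected <- mm + outer(slope, 1 - p)
  n_clip <- sum(!is.na(corrected) & (corrected < 0 | corrected > 1))
  if (n_clip > 0) {
    rlang::inform(sprintf("purity_correct: clipped %d corrected value(s) to [0, 1]", n_clip))
  }
  corrected[which(corrected < 0)] <- 0
  corrected[which(corrected > 1)] <- 1
  attr(corrected, "n_clipped") <- n_clip
  attr(corrected, "dropped_samples") <- dropped
  attr(corrected, "unfitted_probes") <- model$probe[!model$fitted]
  corrected
}
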