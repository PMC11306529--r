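# Paired before/after differential methylation: an interquartile-range
# prefilter, per-probe paired t-tests on per-patient beta deltas,
# Benjamini-Hochberg correction, and a conjunction significance rule
# (adjusted p strictly below alpha AND absolute mean delta strictly above
# min_abs_delta, both thresholds as printed conventions, strict).

#' Interquartile-range prefilter
#'
#' Retains probes whose IQR across samples is strictly greater than
#' `min_iqr`. Quantiles use linear interpolation between order statistics
#' (R's default type 7); missing values are dropped per probe.
#'
#' @param m Probe-by-sample beta matrix.
#' @param min_iqr Strict lower bound on the IQR (default 0.1).
#' @param type Quantile type passed to [stats::quantile()].
#' @return Character vector of retained probe ids.
#' @export
iqr_prefilter <- function(m, min_iqr = 0.1, type = 7) {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0) {
    stop_methrx("iqr_prefilter needs a non-empty matrix")
  }
  iqr <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(0)
    IQR(v, type = type)
  })
  rownames(m)[iqr > min_iqr]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment with enforced monotonicity, capped at 1 (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_methrx("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Paired differential methylation between two timepoints
#'
#' Matches samples into patient pairs via the annotation, forms per-patient
#' beta deltas (after minus before), and runs a two-sided paired t-test per
#' probe. Probes failing the IQR prefilter (computed on the union of the
#' samples entering this comparison) are excluded up front. P-values are
#' BH-adjusted across tested probes; a probe is called significant when
#' `q < alpha` and `|mean_delta| > min_abs_delta`.
#'
#' @param before,after Probe-by-sample beta matrices for the two timepoints.
#' @param annot Cohort annotation mapping `sample_id` to `patient_id`;
#'   patients lacking either timepoint are dropped.
#' @param alpha Significance level on the adjusted p-value (strict).
#' @param min_abs_delta Minimum absolute mean methylation change (strict).
#' @param min_iqr IQR prefilter threshold; set to `NULL` to skip filtering.
#' @return A tibble with `probe`, `n_pairs`, `mean_delta`, `t_stat`, `p`,
#'   `q`, `significant` and `note` (`"ok"`, `"zero_variance"` with p forced
#'   to 1, or `"untested"` when fewer than 2 complete pairs exist). The
#'   number of probes removed by the prefilter is stored in the
#'   `n_prefiltered` attribute.
#' @export
paired_differential <- function(before, after, annot, alpha = 0.05,
                                min_abs_delta = 0.1, min_iqr = 0.1) {
  validate_matrix(before, "beta", "before")
  validate_matrix(after, "beta", "after")
  probes <- intersect(rownames(before), rownames(after))
  if (length(probes) == 0) stop_methrx("no shared probes between matrices")

  pair <- build_pairs(annot, colnames(before), colnames(after))
  if (nrow(pair) == 0) stop_methrx("no patient has samples at both timepoints")
  b <- before[probes, pair$before, drop = FALSE]
  a <- after[probes, pair$after, drop = FALSE]

  n_pre <- 0L
  if (!is.null(min_iqr)) {
    union_m <- cbind(b, a)
    keep <- iqr_prefilter(union_m, min_iqr = min_iqr)
    n_pre <- length(probes) - length(keep)
    probes <- keep
    if (length(probes) == 0) stop_methrx("no probe passes the IQR prefilter")
    b <- b[probes, , drop = FALSE]
    a <- a[probes, , drop = FALSE]
  }

  delta <- a - b
  res <- lapply(seq_len(nrow(delta)), function(i) {
    d <- delta[i, ]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2) {
      return(tibble::tibble(probe = probes[i], n_pairs = n,
                            mean_delta = if (n) mean(d) else NA_real_,
                            t_stat = NA_real_, p = NA_real_, note = "untested"))
    }
    if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {  # constant deltas up to float fuzz
      return(tibble::tibble(probe = probes[i], n_pairs = n, mean_delta = mean(d),
                            t_stat = NA_real_, p = 1, note = "zero_variance"))
    }
    tt <- t.test(d)
    tibble::tibble(probe = probes[i], n_pairs = n, mean_delta = mean(d),
                   t_stat = unname(tt$statistic), p = tt$p.value, note = "ok")
  })
  out <- dplyr::bind_rows(res)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_adjust(out$p[tested])
  out$significant <- !is.na(out$q) & out$q < alpha & abs(out$mean_delta) > min_abs_delta
  out <- dplyr::relocate(out, "note", .after = "significant")
  attr(out, "n_prefiltered") <- n_pre
  attr(out, "n_pairs_used") <- nrow(pair)
  out
}

# Match before/after sample columns into per-patient pairs via annotation.
build_pairs <- function(annot, before_samples, after_samples) {
  map <- setNames(annot$patient_id, annot$sample_id)
  unknown <- setdiff(c(before_samples, after_samples), names(map))
  if (length(unknown)) {
    stop_methrx(paste0("sample(s) missing from annotation: ",
                       paste(head(unknown, 5), collapse = ", ")))
  }
  bt <- tibble::tibble(patient = unname(map[before_samples]), before = before_samples)
  at <- tibble::tibble(patient = unname(map[after_samples]), after = after_samples)
  if (anyDuplicated(bt$patient) || anyDuplicated(at$patient)) {
    stop_methrx("a patient contributes more than one sample to a timepoint")
  }
  dropped <- union(setdiff(bt$patient, at$patient), setdiff(at$patient, bt$patient))
  if (length(dropped)) {
    rlang::inform(paste0("dropping ", length(dropped),
                         " patient(s) lacking one timepoint: ",
                         paste(head(sort(dropped), 5), collapse = ", ")))
  }
  dplyr::inner_join(bt, at, by = "patient")
}
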