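# tidy()/glance() methods (broom conventions) and ggplot2 visualizations
# for the package's fitted objects.

#' @describeIn loo_lasso `tidy()` returns the per-model nonzero
#'   coefficients: one row per (held-out sample, probe).
#' @param x A `loo_signature_fit`.
#' @param ... Unused.
#' @export
tidy.loo_signature_fit <- function(x, ...) {
  dplyr::rename(x$models, term = "probe", estimate = "coef")
}

#' @describeIn loo_lasso `glance()` returns a one-row model summary with the
#'   leave-one-out AUC.
#' @export
glance.loo_signature_fit <- function(x, ...) {
  tibble::tibble(
    n_models = x$n_models,
    mean_n_selected = nrow(x$models) / x$n_models,
    loo_auc = auc_rank(x$loo$probability, x$loo$y))
}

#' @describeIn roc_with_cutoff `tidy()` returns the cutoff table with
#'   sensitivity and specificity per threshold.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @describeIn roc_with_cutoff `glance()` returns a one-row summary: AUC,
#'   optimal cutoff and the operating point there.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, optimal_cutoff = x$optimal_cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @describeIn cocluster `tidy()` returns the feature-to-bicluster
#'   assignment table.
#' @param x A `bicluster_set`.
#' @param ... Unused.
#' @export
tidy.bicluster_set <- function(x, ...) x$assignments

#' @describeIn cocluster `glance()` returns per-bicluster feature counts in
#'   wide form plus `k`.
#' @export
glance.bicluster_set <- function(x, ...) {
  counts <- x$assignments |>
    dplyr::count(.data$bicluster, .data$type) |>
    tidyr::pivot_wider(names_from = "type", values_from = "n", values_fill = 0L) |>
    dplyr::rename(n_probes = "probe", n_genes = "gene")
  dplyr::bind_cols(tibble::tibble(k = x$k), tidyr::nest(counts, sizes = dplyr::everything()))
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_with_cutoff()].
#' @param ... Unused.
#' @return A ggplot: ROC curve with the optimal cutoff marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- object$curve[order(object$curve$specificity), ]
  opt <- tibble::tibble(sensitivity = object$sensitivity,
                        specificity = object$specificity)
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_point(data = opt, color = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the co-clustered affinity matrix
#'
#' Rows (CpGs) and columns (genes) are ordered by bicluster assignment, so
#' planted or discovered block structure shows up as diagonal blocks.
#'
#' @param object A `bicluster_set` from [cocluster()].
#' @param ... Unused.
#' @return A ggplot tile plot of the affinity matrix.
#' @export
autoplot.bicluster_set <- function(object, ...) {
  a <- object$affinity
  asn <- object$assignments
  row_ord <- asn$feature[asn$type == "probe"][order(asn$bicluster[asn$type == "probe"])]
  col_ord <- asn$feature[asn$type == "gene"][order(asn$bicluster[asn$type == "gene"])]
  df <- tibble::as_tibble(expand.grid(probe = row_ord, gene = col_ord,
                                      stringsAsFactors = FALSE))
  df$affinity <- a[cbind(match(df$probe, rownames(a)), match(df$gene, colnames(a)))]
  df$probe <- factor(df$probe, levels = row_ord)
  df$gene <- factor(df$gene, levels = col_ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$probe, fill = .data$affinity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "genes", y = "CpGs", fill = "affinity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Volcano plot of paired differential methylation results
#'
#' @param res A [paired_differential()] result tibble.
#' @param alpha,min_abs_delta Thresholds drawn as guide lines (defaults
#'   match the test's defaults).
#' @return A ggplot of mean delta versus -log10 adjusted p.
#' @export
plot_differential <- function(res, alpha = 0.05, min_abs_delta = 0.1) {
  df <- res[!is.na(res$q), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_delta, y = -log10(.data$q),
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-min_abs_delta, min_abs_delta),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed", color = "grey50") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean delta methylation", y = expression(-log[10]~q)) +
    ggplot2::theme_minimal()
}

#' Bar chart of enrichment results
#'
#' @param res An enrichment tibble (from [hypergeom_gene_sets()],
#'   [region_enrichment()] or [tfbs_enrichment()]).
#' @param top Show at most this many labels, ordered by p-value.
#' @return A ggplot of -log10 p per label, filled by fold enrichment.
#' @export
plot_enrichment <- function(res, top = 20) {
  df <- dplyr::slice_min(res, .data$p, n = top, with_ties = FALSE)
  df$query_label <- factor(df$query_label, levels = rev(df$query_label))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$query_label,
                                   fill = .data$fold)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL, fill = "fold") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
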