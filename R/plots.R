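# ggplot2 views of the main result types.

#' @describeIn fold_change_profiles Spaghetti plot of per-gene mean log
#'   fold-change curves.
#' @param object An `fc_profiles`.
#' @param ... Unused.
#' @param max_genes Subsample cap for readability.
#' @export
autoplot.fc_profiles <- function(object, ..., max_genes = 200) {
  d <- tidy(object)
  genes <- unique(d$gene_id)
  if (length(genes) > max_genes) {
    d <- d[d$gene_id %in% genes[seq_len(max_genes)], ]
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$logfc,
                                  group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::labs(x = "time [h]", y = "log2 fold change",
                  title = object$cell_type)
}

#' @describeIn fit_timecourse_posterior Histogram of posterior probabilities
#'   with the estimated DE prior.
#' @param object An `eb_timecourse_fit`.
#' @param ... Unused.
#' @export
autoplot.eb_timecourse_fit <- function(object, ...) {
  ggplot2::ggplot(object$posterior, ggplot2::aes(.data$posterior_prob)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0) +
    ggplot2::labs(x = "posterior probability of DE", y = "genes",
                  subtitle = paste0("estimated DE prior p = ",
                                    signif(object$p_de, 3)))
}

#' @describeIn fit_curve_mixture Cluster mean curves of log2 fold changes.
#' @param object A `curve_mixture`.
#' @param ... Unused.
#' @export
autoplot.curve_mixture <- function(object, ...) {
  d <- cluster_report(object)$mean_curves
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$logfc,
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time [h]", y = "log2 fold change", colour = "cluster")
}

#' Heatmap of cross-cell-type term association
#'
#' Tile plot of \eqn{-\log(\text{FDR})} per gene set and cell type, the
#' standard view of commonly associated pathways and terms.
#'
#' @param common A result of [common_terms()].
#' @param only_common Restrict rows to the common set (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_common_terms <- function(common, only_common = TRUE) {
  d <- common$table
  if (only_common) d <- d[d$set_id %in% common$common, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$cell_type, .data$set_id,
                                  fill = .data$neg_log_fdr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log(FDR)")
}

#' Heatmap of cluster-to-cluster semantic similarity
#'
#' @param sim_table Output of [cluster_similarity_table()].
#' @param threshold Highly-similar contour (drawn as a text mark).
#' @return A ggplot object.
#' @export
plot_cluster_similarity <- function(sim_table, threshold = 0.7) {
  ggplot2::ggplot(sim_table,
                  ggplot2::aes(.data$cluster_a, .data$cluster_b,
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(!is.na(.data$similarity) & .data$similarity > threshold,
                     "*", "")
    )) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "clusters (cell type A)", y = "clusters (cell type B)",
                  fill = "Wang/BMA")
}
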