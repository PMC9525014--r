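# ggplot2 views of training traces, embeddings and bin quality.

#' Plot a training loss trace
#'
#' @param fit A `vae_fit` or `gnn_fit`.
#' @return A ggplot: loss per epoch (VAE fits additionally facet the
#'   reconstruction and KL terms).
#' @export
plot_loss <- function(fit) {
  tr <- fit$trace
  if (inherits(fit, "vae_fit")) {
    long <- tidyr::pivot_longer(tr, -"epoch", names_to = "term",
                                values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
      ggplot2::labs(x = "epoch", y = NULL, title = "VAE training") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tr, ggplot2::aes(.data$epoch, .data$loss)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "epoch", y = "edge loss", title = "GNN training") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot vae_fit
#' @export
autoplot.vae_fit <- function(object, ...) plot_loss(object)

#' @method autoplot gnn_fit
#' @export
autoplot.gnn_fit <- function(object, ...) plot_loss(object)

#' Plot contig embeddings in two principal components
#'
#' @param embedding Matrix (contigs x dims) or a fitted model.
#' @param color Optional tibble (`contig_id` + one grouping column, e.g.
#'   bins or gold labels) used to color points.
#' @return A ggplot of PC1 vs PC2.
#' @export
plot_embedding <- function(embedding, color = NULL) {
  if (inherits(embedding, c("vae_fit", "gnn_fit"))) embedding <- embedding$embedding
  pc <- stats::prcomp(embedding, rank. = 2)$x
  df <- tibble::tibble(contig_id = rownames(embedding),
                       PC1 = pc[, 1], PC2 = pc[, 2])
  if (!is.null(color)) {
    grp <- setdiff(names(color), "contig_id")[1]
    df <- dplyr::left_join(df, color, by = "contig_id")
    df$group <- factor(df[[grp]])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          color = .data$group)) +
      ggplot2::labs(color = grp)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.8) + ggplot2::theme_minimal()
}

#' Plot per-bin purity vs completeness
#'
#' @param metrics A `label_metrics` object.
#' @return A ggplot; points sized by bin bp, the HQ region outlined.
#' @export
plot_bin_quality <- function(metrics) {
  ggplot2::ggplot(metrics$per_bin,
                  ggplot2::aes(.data$completeness, .data$purity,
                               size = .data$bin_bp)) +
    ggplot2::annotate("rect", xmin = 0.9, xmax = 1, ymin = 0.95, ymax = 1,
                      alpha = 0.15, fill = "forestgreen") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_continuous(labels = scales_bp) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "bp-weighted completeness", y = "bp-weighted purity",
                  size = "bin bp") +
    ggplot2::theme_minimal()
}

scales_bp <- function(x) ifelse(x >= 1e6, sprintf("%.1f Mb", x / 1e6),
                                sprintf("%.0f kb", x / 1e3))

#' @method autoplot label_metrics
#' @export
autoplot.label_metrics <- function(object, ...) plot_bin_quality(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
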