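#' Heat map of a pairwise identity matrix
#'
#' The standard visual check of the anchor-by-genus / RBD-by-serogroup
#' contrast: within-group blocks of high identity stand out against a low
#' background.
#'
#' @param identity Matrix from [identity_matrix()].
#' @param order_ids Optional id ordering (e.g. grouped by genus or
#'   serogroup).
#' @return A ggplot object.
#' @export
plot_identity_heatmap <- function(identity, order_ids = NULL) {
  ids <- rownames(identity)
  if (!is.null(order_ids)) ids <- intersect(order_ids, ids)
  df <- tidyr::expand_grid(query = ids, subject = ids)
  df$identity <- identity[cbind(df$query, df$subject)]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$query, levels = ids),
    y = factor(.data$subject, levels = rev(ids)),
    fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "% identity") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Pairwise identity (",
                                 attr(identity, "region") %||% "full",
                                 " region)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conservation profile of a flank alignment
#'
#' Per-column mean pairwise identity with detected motif spans shaded;
#' the visual counterpart of [scan_conserved_windows()].
#'
#' @param aln A `star_msa` alignment.
#' @param hits Optional motif hits for the same alignment.
#' @param cfg An [rbp_config()] (for the threshold line).
#' @return A ggplot object.
#' @export
plot_motif_conservation <- function(aln, hits = NULL, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  prof <- column_identity_profile(msa_matrix(aln))
  df <- tibble(column = seq_along(prof), identity = 100 * prof)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$identity)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_hline(yintercept = cfg$motif_min_identity,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "alignment column", y = "mean pairwise identity (%)") +
    ggplot2::theme_minimal()
  if (!is.null(hits) && nrow(hits)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = hits$start_col - 0.5, xmax = hits$end_col + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Stacked-bar view of the dataset ledger
#'
#' @param object An `rbp_ledger`.
#' @param ... Unused.
#' @return A ggplot object showing the terminal category of every RBP.
#' @method autoplot rbp_ledger
#' @export
autoplot.rbp_ledger <- function(object, ...) {
  df <- dplyr::count(object$record_categories, .data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = "RBPs", y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "RBPs", fill = "outcome") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
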