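#' Plot a ROC curve
#' @param object A `roc_curve` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot gene importance (mean decrease in accuracy)
#'
#' @param importance Tibble from [permutation_importance()].
#' @param mda_threshold Selection threshold drawn as a reference line.
#' @param top_n Show at most this many genes (by importance).
#' @return A ggplot.
#' @export
plot_importance <- function(importance, mda_threshold = 4, top_n = 30L) {
  dat <- importance |>
    dplyr::slice_max(.data$mean_mda, n = top_n, with_ties = FALSE) |>
    dplyr::mutate(gene = stats::reorder(.data$gene, .data$mean_mda))
  ggplot2::ggplot(dat, ggplot2::aes(.data$mean_mda, .data$gene)) +
    ggplot2::geom_col(fill = "#2166AC", width = 0.7) +
    ggplot2::geom_vline(xintercept = mda_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Mean decrease in accuracy (points)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot consensus probabilities of a classification
#' @param object A `classification_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classification_result <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(.data$mean_prob, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(hypoxic = "#B2182B",
                                          normoxic = "#2166AC"),
                               na.value = "grey70") +
    ggplot2::labs(x = "Mean hypoxia probability", y = "Samples",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Map per-spot hypoxia probability on the spatial grid
#'
#' @param spots Tibble from [classify_spots()] with `row`/`col` coordinates.
#' @return A ggplot tile map, blank spots in grey.
#' @export
plot_spatial <- function(spots) {
  stopifnot(all(c("row", "col", "mean_prob") %in% names(spots)))
  dat <- dplyr::mutate(spots,
                       shown = ifelse(.data$blank, NA_real_, .data$mean_prob))
  ggplot2::ggplot(dat, ggplot2::aes(.data$col, .data$row,
                                    fill = .data$shown)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                  high = "#B2182B", midpoint = 0.5,
                                  limits = c(0, 1), na.value = "grey80",
                                  name = "P(hypoxic)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
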