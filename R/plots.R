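# ggplot2 graphics for fitted objects.

#' Distribution of per-fold metrics of a nested cross-validation
#'
#' @param object A `pk_cv`.
#' @param metric Metric column to plot (default `"r2"`).
#' @param ... Unused.
#' @return A ggplot: boxplot of the metric over evaluation folds.
#' @method autoplot pk_cv
#' @export
autoplot.pk_cv <- function(object, metric = "r2", ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data[[metric]])) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("%d-fold nested cross-validation",
                                  nrow(d))) +
    ggplot2::theme_minimal()
}

#' Fold-error versus similarity curve
#'
#' The fitted kernel-ridge curve over the similarity range, with the
#' binned mean-fold-error points it was fit to and the applicability-
#' domain threshold.
#'
#' @param object A `fold_error_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fold_error_model
#' @export
autoplot.fold_error_model <- function(object, ...) {
  curve <- fold_error_curve(object)
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$similarity, y = .data$mean_fe)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$fold_error),
                       linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$ad_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "mean 5-NN Tanimoto similarity to training data",
                  y = "mean fold error") +
    ggplot2::theme_minimal()
}

#' Compare feature combinations for one endpoint
#'
#' Paired per-fold metric distributions across the trained feature
#' combinations of a human model set.
#'
#' @param model_set A `human_model_set`.
#' @param endpoint Endpoint to show.
#' @param metric Per-fold metric column (default `"r2"`).
#' @return A ggplot.
#' @export
plot_combo_comparison <- function(model_set, endpoint, metric = "r2") {
  combo_tbl <- feature_combos()
  d <- purrr::map_dfr(names(model_set$cv[[endpoint]]), function(cid) {
    tidy(model_set$cv[[endpoint]][[cid]]) |>
      dplyr::mutate(combo = combo_tbl$label[[as.integer(cid)]])
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combo, y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric, title = endpoint) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Chemical-space projection plot
#'
#' @param projection Result of [pca_projection()].
#' @return A ggplot of the first two principal components coloured by
#'   dataset.
#' @export
plot_chemical_space <- function(projection) {
  ggplot2::ggplot(projection$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$dataset)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * projection$variance_explained[[1]]),
      y = sprintf("PC2 (%.0f%%)", 100 * projection$variance_explained[[2]])) +
    ggplot2::theme_minimal()
}
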