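# ggplot2 visualizations

slice_df <- function(values, spacing, z) {
  d <- dim(values)
  sl <- values[, , z]
  tidyr::expand_grid(j = seq_len(d[2]), i = seq_len(d[1])) |>
    dplyr::mutate(x = (.data$i - 1) * spacing[1],
                  y = (.data$j - 1) * spacing[2],
                  value = as.vector(sl))
}

#' Plot an axial slice of a decision map
#'
#' Positive decision values push the patient toward class 1, negative
#' toward class 0; the background (outside the ROI) is blank.
#'
#' @param object a `decision_map`.
#' @param z slice index (default: the slice with the most ROI voxels).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot decision_map
#' @export
autoplot.decision_map <- function(object, z = NULL, ...) {
  d <- dim(object$values)
  if (is.null(z)) z <- which.max(apply(!is.na(object$values), 3, sum))
  df <- slice_df(object$values, object$spacing_mm, z)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = "DV") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Decision map (slice %d)", z),
      subtitle = sprintf("mean DV %.3f, probability %.3f",
                         object$mean_dv, object$probability),
      x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a voxel-wise feature map
#'
#' @param object a `feature_map_set`.
#' @param feature map name (e.g. `"GLCM_Contrast"`).
#' @param z slice index (default: most ROI voxels).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot feature_map_set
#' @export
autoplot.feature_map_set <- function(object, feature = names(object$maps)[1],
                                     z = NULL, ...) {
  a <- object$maps[[feature]]
  if (is.null(a)) stop("unknown map: ", feature, call. = FALSE)
  if (is.null(z)) z <- which.max(apply(!is.na(a), 3, sum))
  df <- slice_df(a, object$spacing_mm, z)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = feature) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s %s (slice %d)", object$modality,
                                  feature, z),
                  x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' Plot the grid-search ASB landscape
#'
#' Mean cross-validated ASB per (C, subset size), with the selected
#' configuration highlighted.
#'
#' @param object a `grid_search_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot grid_search_result
#' @export
autoplot.grid_search_result <- function(object, ...) {
  df <- object$results
  sel <- object$selected
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$k), factor(signif(.data$C, 3)),
                                   fill = .data$mean_asb)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = sel, shape = 21, size = 3, fill = "white") +
    ggplot2::scale_fill_viridis_c(name = "mean ASB") +
    ggplot2::labs(x = "number of selected features", y = "C") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' Histogram of the null best cross-validated ASB scores with the observed
#' score marked.
#'
#' @param object a `permutation_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble(null_score = object$null_scores)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, color = "#B2182B",
                        linewidth = 1) +
    ggplot2::labs(x = "null best mean ASB", y = "count",
                  title = sprintf("Permutation test: p = %.4g",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot bagged coefficients with bootstrap variability
#'
#' @param object a `bagged_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot bagged_model
#' @export
autoplot.bagged_model <- function(object, ...) {
  df <- object$coef_summary
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term,
                                                  .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$estimate - .data$sd,
                                          xmax = .data$estimate + .data$sd)) +
    ggplot2::labs(x = "standardized coefficient (mean +/- SD)", y = NULL) +
    ggplot2::theme_minimal()
}
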