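#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a voxel grid slice
#'
#' Heatmap of one axial slice of a PET volume (default: the middle slice),
#' in physical mm coordinates.
#'
#' @param object a [voxel_grid].
#' @param slice slice index along the third axis; default middle.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_grid <- function(object, slice = NULL, ...) {
  dm <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(dm[3L] / 2)
  df <- tidyr::expand_grid(ix = seq_len(dm[1L]), iy = seq_len(dm[2L]))
  df$suv <- object$values[cbind(df$ix, df$iy, slice)]
  df$x <- (df$ix - 0.5) * object$spacing[1L]
  df$y <- (df$iy - 0.5) * object$spacing[2L]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$suv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "SUV", option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]",
                  title = sprintf("axial slice %d", slice)) +
    ggplot2::theme_minimal()
}

#' Plot a screening report
#'
#' Dot-and-interval plot of the oriented AUC per evaluable feature, with the
#' pre-selection gate marked; final predictors are highlighted.
#'
#' @param object a `screening_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.screening_report <- function(object, ...) {
  df <- dplyr::filter(object$results, .data$evaluable)
  df$status <- dplyr::case_when(
    df$final ~ "final",
    df$preselected ~ "pre-selected",
    TRUE ~ "excluded"
  )
  df$feature <- stats::reorder(df$feature, df$auc)
  ggplot2::ggplot(df, ggplot2::aes(.data$auc, .data$feature, color = .data$status)) +
    ggplot2::geom_vline(xintercept = object$settings$auc_min, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, color = "grey70") +
    {
      if (!all(is.na(df$auc_ci_low))) {
        ggplot2::geom_errorbarh(
          ggplot2::aes(xmin = .data$auc_ci_low, xmax = .data$auc_ci_high),
          height = 0.2
        )
      }
    } +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(
      final = "#B2182B", `pre-selected` = "#2166AC", excluded = "grey60"
    )) +
    ggplot2::labs(x = "AUC (oriented)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of the final predictors by outcome
#'
#' Per-class box plots of the final (or any chosen) features, one panel per
#' feature on free scales.
#'
#' @param data the screened feature table.
#' @param report a `screening_report` fitted on `data`.
#' @param features features to plot; default the report's final set.
#' @return A ggplot object.
#' @export
plot_predictor_boxplots <- function(data, report, features = NULL) {
  if (is.null(features)) features <- report$final
  if (length(features) == 0L) stopf("no features to plot")
  outcome <- report$settings$outcome
  long <- tidyr::pivot_longer(
    data[c(outcome, features)],
    cols = dplyr::all_of(features),
    names_to = "feature", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data[[outcome]], .data$value,
                                     fill = .data[[outcome]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
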