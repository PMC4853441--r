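#' @importFrom ggplot2 ggplot aes geom_raster geom_tile facet_wrap coord_fixed
#'   scale_fill_viridis_c scale_fill_gradient2 scale_fill_manual labs autoplot
#'   theme_minimal geom_point geom_errorbarh geom_vline
NULL

#' @export
ggplot2::autoplot

default_slices <- function(grid, n = 6) {
  unique(round(seq(2, grid$dims[3] - 1, length.out = n)))
}

slice_df <- function(grid, values, slices, keep = NULL) {
  df <- voxel_tibble(grid, values, keep = keep)
  df <- df[df$k %in% (slices - 1L), ]
  df$slice <- factor(paste0("z = ", signif(df$z, 3)),
                     levels = paste0("z = ", signif(sort(unique(df$z)), 3)))
  df
}

#' Axial slice mosaic of a lesion prevalence map
#'
#' @param object A `count_map`.
#' @param slices 1-based axial slice indices (default: 6 evenly spaced).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.count_map <- function(object, slices = default_slices(object$grid), ...) {
  df <- slice_df(object$grid, list(count = object$counts), slices,
                 keep = object$counts > 0)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$count)) +
    geom_raster() +
    facet_wrap(~slice, nrow = 1) +
    coord_fixed() +
    scale_fill_viridis_c(option = "inferno") +
    labs(title = "Lesion prevalence",
         subtitle = sprintf("%d subjects; display threshold %d",
                            object$n_subjects, object$display_threshold),
         x = "x (mm)", y = "y (mm)", fill = "patients") +
    theme_minimal()
}

#' Axial slice mosaic of a voxel-wise statistic map
#'
#' Significant voxels (FDR) are drawn over the signed statistic background.
#'
#' @param object A `stat_map`.
#' @param slices Axial slice indices.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stat_map <- function(object, slices = default_slices(object$grid), ...) {
  df <- slice_df(object$grid,
                 list(statistic = object$statistic, significant = object$significant),
                 slices, keep = object$tested)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$statistic)) +
    geom_raster() +
    geom_point(data = df[df$significant, ], shape = ".", colour = "red") +
    facet_wrap(~slice, nrow = 1) +
    coord_fixed() +
    scale_fill_gradient2(low = "blue", mid = "grey90", high = "darkgreen") +
    labs(title = sprintf("VLSM: %s (%s, %s-tailed)", object$outcome,
                         object$statistic_kind, object$tails),
         subtitle = sprintf("q = %g, realized cutoff %.3g; significant voxels in red",
                            object$q, object$fdr_cutoff),
         x = "x (mm)", y = "y (mm)") +
    theme_minimal()
}

#' Axial slice mosaic of a significance overlap map
#'
#' @param object An `overlap_map`.
#' @param slices Axial slice indices.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_map <- function(object, slices = default_slices(object$grid), ...) {
  df <- slice_df(object$grid, list(code = object$category), slices,
                 keep = object$category > 0L)
  df$category <- factor(c("a_only", "b_only", "both")[df$code],
                        levels = c("a_only", "b_only", "both"),
                        labels = c(object$outcomes["a"], object$outcomes["b"], "both"))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$category)) +
    geom_raster() +
    facet_wrap(~slice, nrow = 1) +
    coord_fixed() +
    scale_fill_manual(values = c("red", "green3", "yellow")) +
    labs(title = "Significant voxels per outcome", x = "x (mm)", y = "y (mm)",
         fill = NULL) +
    theme_minimal()
}

#' Axial slice mosaic of a lesion subtraction map
#'
#' @param object A `subtraction_map`.
#' @param slices Axial slice indices.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subtraction_map <- function(object, slices = default_slices(object$grid), ...) {
  df <- slice_df(object$grid,
                 list(percent_difference = object$percent_difference), slices,
                 keep = object$percent_difference != 0)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$percent_difference)) +
    geom_raster() +
    facet_wrap(~slice, nrow = 1) +
    coord_fixed() +
    scale_fill_gradient2(low = "blue", mid = "grey95", high = "red",
                         limits = c(-100, 100)) +
    labs(title = sprintf("Lesion subtraction: %s", object$test),
         subtitle = sprintf("%d impaired vs %d normal; impaired-minus-normal prevalence",
                            object$n_impaired, object$n_normal),
         x = "x (mm)", y = "y (mm)", fill = "points") +
    theme_minimal()
}

#' Forest plot of ROI regression coefficients
#'
#' Unstandardized coefficients B (change in z score per ml of regional
#' infarct volume) with 95% CIs per region and outcome.
#'
#' @param roi_models Stacked [glance.roi_model_fit()] rows
#'   (e.g. `run$roi_models`).
#' @return A ggplot.
#' @export
plot_roi_coefficients <- function(roi_models) {
  df <- roi_models |>
    mutate(model = ifelse(.data$adjusted_for_total_volume,
                          "adjusted for total volume", "unadjusted"))
  ggplot(df, aes(x = .data$B, y = .data$region_volume, colour = .data$outcome)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, position = ggplot2::position_dodge(0.5)) +
    geom_point(position = ggplot2::position_dodge(0.5)) +
    facet_wrap(~model) +
    labs(x = "B (z score per ml)", y = NULL, colour = "outcome") +
    theme_minimal()
}
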