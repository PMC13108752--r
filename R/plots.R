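#' Plot methods for analysis results
#'
#' `autoplot()` methods render the standard figures: per-group error box
#' plots by method (whiskers at 1.5 IQR), the Dice-vs-voxel-size curve, and
#' a 2D slice view of gesture-space occupancy overlap.
#'
#' @param object An `error_table`, `dice_curve`, or `occupancy_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hpeval-autoplot
NULL

#' @rdname hpeval-autoplot
#' @export
#' @method autoplot error_table
autoplot.error_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$e,
                                       fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "Euclidean distance to MoCap (mm)",
                  fill = "Method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname hpeval-autoplot
#' @export
#' @method autoplot dice_curve
autoplot.dice_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voxel_size_mm, y = .data$dice)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "Voxel size (mm)", y = "Dice coefficient") +
    ggplot2::theme_minimal()
}

#' Plot a gesture-space occupancy comparison (axial slice counts)
#'
#' Collapses two occupancy sets along one axis and shows which columns of
#' voxels are occupied by the reference only, the method only, or both.
#'
#' @param A,B `occupancy_set`s (reference, method).
#' @param axis Axis to collapse: `"z"` (default), `"x"` or `"y"`.
#' @return A ggplot object.
#' @export
plot_occupancy_overlap <- function(A, B, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  keep <- setdiff(c("ix", "iy", "iz"), paste0("i", axis))
  a2 <- distinct(as_tibble(A)[, keep])
  b2 <- distinct(as_tibble(B)[, keep])
  both <- inner_join(a2, b2, by = keep)
  df <- bind_rows(
    mutate(dplyr::anti_join(a2, both, by = keep), set = "reference only"),
    mutate(dplyr::anti_join(b2, both, by = keep), set = "method only"),
    mutate(both, set = "both")
  )
  names(df)[1:2] <- c("h", "v")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v, fill = .data$set)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(`both` = "#2E8B57",
                                          `reference only` = "#C0392B",
                                          `method only` = "#2980B9")) +
    ggplot2::labs(x = paste0("voxel index (", keep[1], ")"),
                  y = paste0("voxel index (", keep[2], ")"), fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
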