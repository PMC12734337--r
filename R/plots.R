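#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a deep-gray-matter area profile
#'
#' Per-slice deep-gray-matter cross-sectional area with the selected center
#' slice marked, the visual counterpart of [select_center_slice()].
#'
#' @param object A `vm_area_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vm_area_profile <- function(object, ...) {
  df <- data.frame(slice = seq_along(object), area_mm2 = as.numeric(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$area_mm2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial slice", y = "deep gray matter area (mm²)")
  if (any(df$area_mm2 > 0))
    p <- p + ggplot2::geom_vline(xintercept = which.max(df$area_mm2),
                                 linetype = "dashed", colour = "red")
  p
}

#' Plot a measured slice with its ventricle split
#'
#' Shows the ventricle pixels of an axial label slice colored by the side
#' assigned by [split_ventricles()], with deep gray matter in gray.
#'
#' @param object A `vm_label_slice`.
#' @param split_axis Passed to [split_ventricles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vm_label_slice <- function(object, split_axis = "x", ...) {
  d <- object$data
  sp <- object$in_plane_spacing
  idx <- which(d > 0L, arr.ind = TRUE)
  df <- data.frame(x = (idx[, 1] - 0.5) * sp[1], y = (idx[, 2] - 0.5) * sp[2],
                   label = d[idx])
  df$tissue <- ifelse(df$label == 2L, "deep gray matter", "ventricle")
  if (any(d == 1L)) {
    split <- split_ventricles(d == 1L, split_axis = split_axis)
    vent <- df$label == 1L
    side <- ifelse(split$left_mask[idx[vent, , drop = FALSE]], "left ventricle",
                   "right ventricle")
    df$tissue[vent] <- side
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$tissue)) +
    ggplot2::geom_tile(width = sp[1], height = sp[2]) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = NULL)
}

#' @importFrom rlang .data
NULL
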