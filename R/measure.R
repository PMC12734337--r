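#' Adaptive left/right ventricle partitioning
#'
#' Splits a binary ventricle mask into left and right parts. The detector
#' projects the mask onto the left-right axis (sums along the
#' anterior-posterior axis, one value per column) and looks for a
#' discontinuity: a run of empty columns strictly between occupied columns.
#' If at least one such interior zero run exists, the mask is split at the
#' midpoint of the longest run (ties broken toward the run closest to the
#' mask's horizontal center) — the "gap" method. Otherwise the mask is split
#' into two equal halves at the horizontal midpoint of its bounding box.
#' The two output masks always partition the input exactly.
#'
#' @param vmask Binary matrix (or `vm_label_slice`, in which case label 1 is
#'   taken as ventricle); axis 1 (rows of the matrix) is the left-right axis.
#' @param split_axis `"x"` (default) to split along axis 1, `"y"` to split
#'   along axis 2.
#' @return A `vm_ventricle_split`: list with binary matrices `left_mask`,
#'   `right_mask`, the `method` (`"gap"` or `"equal_halves"`) and the
#'   `split_column` (last column index assigned to the left part, or the gap
#'   midpoint).
#' @export
split_ventricles <- function(vmask, split_axis = c("x", "y")) {
  split_axis <- match.arg(split_axis)
  mask <- as_binary_mask(vmask)
  if (!any(mask)) stop_vm_anatomy("empty ventricle mask: nothing to split")
  work <- if (split_axis == "y") t(mask) else mask
  profile <- rowSums(work)                       # occupancy per left-right column
  occ <- which(profile > 0)
  lo <- min(occ); hi <- max(occ)
  inner <- profile[lo:hi]
  runs <- zero_runs(inner)
  if (nrow(runs) > 0) {
    # longest interior zero run; ties -> run whose midpoint is most central
    runs$len <- runs$end - runs$start + 1L
    center <- (length(inner) + 1) / 2
    runs$dist <- abs((runs$start + runs$end) / 2 - center)
    runs <- runs[order(-runs$len, runs$dist, runs$start), , drop = FALSE]
    gap_mid <- lo - 1L + as.integer(floor((runs$start[1] + runs$end[1]) / 2))
    method <- "gap"; split_col <- gap_mid
  } else {
    method <- "equal_halves"
    split_col <- as.integer(floor((lo + hi) / 2))
  }
  left <- work; left[seq_len(nrow(work)) > split_col, ] <- FALSE
  right <- work & !left
  if (split_axis == "y") { left <- t(left); right <- t(right) }
  structure(list(left_mask = left, right_mask = right,
                 method = method, split_column = split_col),
            class = "vm_ventricle_split")
}

as_binary_mask <- function(x, label = 1L) {
  if (inherits(x, "vm_label_slice")) x$data == label
  else if (is.matrix(x)) x > 0
  else stop("expected a matrix or vm_label_slice", call. = FALSE)
}

# interior zero runs of a vector whose first and last entries are nonzero
zero_runs <- function(v) {
  z <- v == 0
  if (!any(z)) return(data.frame(start = integer(), end = integer()))
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.vm_ventricle_split <- function(x, ...) {
  cat(sprintf("<fetalvm ventricle split> method %s at column %d (left %d px, right %d px)\n",
              x$method, x$split_column, sum(x$left_mask), sum(x$right_mask)))
  invisible(x)
}

#' Minimum-area bounding rectangle of a binary mask
#'
#' Fits the minimal-area oriented rectangle around the foreground pixels.
#' The orientation is the one minimizing the bounding-box area of the pixel
#' *centers* over all orientations (exact, via the rotating-calipers property
#' that the optimum is flush with a convex-hull edge); the sides are then
#' padded by the support of one dx-by-dy pixel square in each rectangle-axis
#' direction, so the reported rectangle contains every foreground pixel's
#' full physical square and a single pixel has extent dx x dy rather than
#' zero. Coordinates are scaled to mm before fitting so anisotropic spacing
#' does not bias the orientation.
#'
#' @param mask Binary matrix (axis 1 = x, axis 2 = y) or `vm_label_slice`.
#' @param spacing Pixel spacing `(dx, dy)` in mm (taken from the slice when
#'   a `vm_label_slice` is given).
#' @return A `vm_bounding_rect`: list with `center` (mm), `angle` (degrees in
#'   `[0, 90)`, orientation of the long side), `side_a` >= `side_b` (mm).
#' @export
min_bounding_rect <- function(mask, spacing = c(1, 1)) {
  if (inherits(mask, "vm_label_slice")) {
    spacing <- mask$in_plane_spacing
    mask <- mask$data == 1L
  }
  mask <- mask > 0
  if (!any(mask)) stop_vm_anatomy("empty mask: no bounding rectangle")
  idx <- which(mask, arr.ind = TRUE)
  # pixel (i, j) occupies [(i-1)dx, i dx] x [(j-1)dy, j dy]; the rectangle
  # orientation is fitted to the pixel centers, then each side is padded by
  # the pixel square's support in that direction, so the result still
  # contains every pixel's full physical square. Fitting orientation on the
  # padded hull instead would bias small rotations toward the image axes.
  centers <- cbind((idx[, 1] - 0.5) * spacing[1], (idx[, 2] - 0.5) * spacing[2])
  hull <- centers[grDevices::chull(centers), , drop = FALSE]
  angles <- 0
  if (nrow(hull) > 1L) {
    edges <- diff(rbind(hull, hull[1, , drop = FALSE]))
    angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  }
  best <- NULL
  for (theta in angles) {
    u <- c(cos(theta), sin(theta)); v <- c(-sin(theta), cos(theta))
    rng_u <- range(hull %*% u); rng_v <- range(hull %*% v)
    ext <- c(diff(rng_u), diff(rng_v))
    area <- prod(ext)
    if (is.null(best) || area < best$area - 1e-12) {
      best <- list(area = area, ext = ext, theta = theta,
                   center = u * mean(rng_u) + v * mean(rng_v))
    }
  }
  # support width of one dx-by-dy pixel square along each rectangle axis
  pad <- c(spacing[1] * abs(cos(best$theta)) + spacing[2] * abs(sin(best$theta)),
           spacing[1] * abs(sin(best$theta)) + spacing[2] * abs(cos(best$theta)))
  best$ext <- best$ext + pad
  side_a <- max(best$ext); side_b <- min(best$ext)
  # report the orientation of the long side, normalized to [0, 90)
  ang <- best$theta * 180 / pi
  if (best$ext[2] > best$ext[1]) ang <- ang + 90
  ang <- ang %% 90
  structure(list(center = best$center, angle = ang,
                 side_a = side_a, side_b = side_b),
            class = "vm_bounding_rect")
}

#' @export
print.vm_bounding_rect <- function(x, ...) {
  cat(sprintf("<fetalvm bounding rect> %.2f x %.2f mm at (%.2f, %.2f), %.1f deg\n",
              x$side_a, x$side_b, x$center[1], x$center[2], x$angle))
  invisible(x)
}

#' Ventricular width of a fitted bounding rectangle
#'
#' The atrial width is transverse to the ventricle's long axis, so by default
#' the short side of the minimum-area rectangle is reported; `"long_side"`
#' returns the long side instead.
#'
#' @param rect A `vm_bounding_rect`.
#' @param convention `"short_side"` (default) or `"long_side"`.
#' @return Width in mm.
#' @export
ventricle_width <- function(rect, convention = c("short_side", "long_side")) {
  convention <- match.arg(convention)
  stopifnot(inherits(rect, "vm_bounding_rect"))
  if (convention == "short_side") rect$side_b else rect$side_a
}

#' Measure ventricular widths on one axial slice
#'
#' Runs the full 2D chain: adaptive left/right split, per-side minimum
#' bounding rectangle, per-side width, final width as the maximum of the two
#' sides. A side left empty by the split is reported as 0 mm (unilateral
#' enlargement must not error).
#'
#' @param vmask A `vm_label_slice` (label 1 = ventricles) or binary matrix.
#' @param spacing Pixel spacing `(dx, dy)` in mm when a matrix is given.
#' @param convention Width convention, see [ventricle_width()].
#' @param split_axis Passed to [split_ventricles()].
#' @return A `vm_measurement` with `left_width_mm`, `right_width_mm`,
#'   `final_width_mm`, `split_method`, `slice_index` (volume/volume_cm3 NA).
#' @export
measure_slice <- function(vmask, spacing = c(1, 1),
                          convention = c("short_side", "long_side"),
                          split_axis = c("x", "y")) {
  convention <- match.arg(convention)
  split_axis <- match.arg(split_axis)
  slice_index <- NA_integer_
  if (inherits(vmask, "vm_label_slice")) {
    spacing <- vmask$in_plane_spacing
    slice_index <- vmask$slice_index
    mask <- vmask$data == 1L
  } else mask <- vmask > 0
  if (!any(mask)) stop_vm_anatomy("no ventricle pixels in slice")
  split <- split_ventricles(mask, split_axis = split_axis)
  side_width <- function(m) {
    if (!any(m)) return(0)
    ventricle_width(min_bounding_rect(m, spacing), convention)
  }
  left <- side_width(split$left_mask)
  right <- side_width(split$right_mask)
  new_vm_measurement(left_width_mm = left, right_width_mm = right,
                     volume_cm3 = NA_real_, slice_index = slice_index,
                     split_method = split$method)
}

#' Total ventricular volume of a simplified mask
#'
#' Label-1 voxel count times the voxel volume, in cm^3. An empty mask gives 0.
#'
#' @param mask A simplified `vm_label_volume`.
#' @return Volume in cm^3.
#' @export
ventricle_volume <- function(mask) {
  stopifnot(is_label_volume(mask))
  if (!is_simplified(mask))
    stop("mask must be simplified to labels {0, 1, 2}", call. = FALSE)
  sum(mask$data == 1L) * prod(mask$spacing) / 1000
}

#' Measure a 3D simplified mask
#'
#' The 3D entry point: selects the axial measurement plane by maximal
#' deep-gray-matter area, measures left/right/final widths on that slice, and
#' computes the total ventricular volume over the whole volume. A volume with
#' no ventricle voxels at the measurement slice (or anywhere) yields widths of
#' 0 mm rather than an error; a volume with no deep gray matter errors, since
#' no measurement plane exists.
#'
#' @param vol_mask A simplified `vm_label_volume` containing deep gray matter.
#' @param convention,split_axis See [measure_slice()].
#' @return A `vm_measurement`.
#' @export
measure_volume <- function(vol_mask, convention = c("short_side", "long_side"),
                           split_axis = c("x", "y")) {
  convention <- match.arg(convention)
  split_axis <- match.arg(split_axis)
  stopifnot(is_label_volume(vol_mask))
  if (!is_simplified(vol_mask))
    stop("mask must be simplified to labels {0, 1, 2}", call. = FALSE)
  center <- select_center_slice(dgm_area_profile(vol_mask))
  vol_cm3 <- ventricle_volume(vol_mask)
  plane <- extract_slices(vol_mask, center)[[1]]
  if (!any(plane$data == 1L)) {
    m <- new_vm_measurement(left_width_mm = 0, right_width_mm = 0,
                            volume_cm3 = vol_cm3, slice_index = center,
                            split_method = NA_character_)
    return(m)
  }
  m <- measure_slice(plane, convention = convention, split_axis = split_axis)
  m$volume_cm3 <- vol_cm3
  m
}

new_vm_measurement <- function(left_width_mm, right_width_mm, volume_cm3,
                               slice_index, split_method) {
  structure(list(left_width_mm = left_width_mm,
                 right_width_mm = right_width_mm,
                 final_width_mm = max(left_width_mm, right_width_mm),
                 volume_cm3 = volume_cm3,
                 slice_index = as.integer(slice_index),
                 split_method = split_method),
            class = "vm_measurement")
}

#' @export
print.vm_measurement <- function(x, ...) {
  cat("<fetalvm measurement>\n")
  cat(sprintf("  width (mm): left %.2f, right %.2f, final %.2f\n",
              x$left_width_mm, x$right_width_mm, x$final_width_mm))
  cat(sprintf("  volume: %s cm^3   slice: %s   split: %s\n",
              ifelse(is.na(x$volume_cm3), "NA", sprintf("%.2f", x$volume_cm3)),
              ifelse(is.na(x$slice_index), "NA", x$slice_index),
              ifelse(is.na(x$split_method), "NA", x$split_method)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ventricle measurement into a one-row tibble
#'
#' @param x A `vm_measurement`.
#' @param ... Unused.
#' @return A tibble with columns `left_width_mm`, `right_width_mm`,
#'   `final_width_mm`, `volume_cm3`, `slice_index`, `split_method`.
#' @export
tidy.vm_measurement <- function(x, ...) {
  tibble::tibble(left_width_mm = x$left_width_mm,
                 right_width_mm = x$right_width_mm,
                 final_width_mm = x$final_width_mm,
                 volume_cm3 = x$volume_cm3,
                 slice_index = x$slice_index,
                 split_method = x$split_method)
}
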