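#' Deep-gray-matter cross-sectional area profile
#'
#' Computes, for every axial slice of a simplified mask, the cross-sectional
#' area of deep gray matter (label 2) in mm^2: the label-2 voxel count of the
#' slice times the in-plane pixel area. This profile drives selection of the
#' measurement plane: in fetal MRI the ventricular (atrial) width is read on
#' the axial plane through the thalami, where the deep gray matter is largest.
#'
#' @param mask A simplified `vm_label_volume` (labels in `{0, 1, 2}`).
#' @return A `vm_area_profile`: numeric vector of per-slice areas (mm^2) with
#'   attributes `spacing`; length equals the number of axial slices.
#' @export
dgm_area_profile <- function(mask) {
  stopifnot(is_label_volume(mask))
  if (!is_simplified(mask))
    stop("mask must be simplified to labels {0, 1, 2}; see remap_labels()",
         call. = FALSE)
  pix_area <- mask$spacing[1] * mask$spacing[2]
  counts <- apply(mask$data == 2L, 3, sum)
  structure(as.numeric(counts) * pix_area,
            spacing = mask$spacing, class = "vm_area_profile")
}

#' Select the axial measurement slice
#'
#' Returns the index of the slice with the largest deep-gray-matter area;
#' ties are broken toward the smallest index. Errors when no deep gray matter
#' is present anywhere (no measurement plane can be defined).
#'
#' @param profile A `vm_area_profile` or plain numeric vector of areas.
#' @return 1-based slice index of the maximal area.
#' @export
select_center_slice <- function(profile) {
  areas <- as.numeric(profile)
  if (length(areas) == 0L || all(areas <= 0))
    stop_vm_anatomy("no deep gray matter present: cannot select a measurement slice")
  which.max(areas)
}

#' Symmetric slice window around a center slice
#'
#' Builds the inclusive index range `center - half_width .. center + half_width`
#' clipped to the volume (no padding and no shifting at the boundaries), so an
#' interior center yields `2 * half_width + 1` slices.
#'
#' @param center 1-based center slice index.
#' @param half_width Number of slices taken on each side (default 12, giving
#'   a 25-slice stack).
#' @param depth Number of axial slices in the volume.
#' @return A `vm_slice_window`: list with `center`, `half_width`, `indices`.
#' @export
select_window <- function(center, half_width = 12L, depth) {
  center <- as.integer(center); half_width <- as.integer(half_width)
  depth <- as.integer(depth)
  if (half_width < 0L) stop("half_width must be >= 0", call. = FALSE)
  if (center < 1L || center > depth)
    stop("center slice outside the volume", call. = FALSE)
  indices <- max(1L, center - half_width):min(depth, center + half_width)
  structure(list(center = center, half_width = half_width, indices = indices),
            class = "vm_slice_window")
}

#' @export
print.vm_slice_window <- function(x, ...) {
  cat(sprintf("<fetalvm slice window> center %d, +/-%d -> %d slices (%d..%d)\n",
              x$center, x$half_width, length(x$indices),
              min(x$indices), max(x$indices)))
  invisible(x)
}

#' Extract axial slices from a volume
#'
#' Pulls the requested axial planes, in the given order, each carrying its
#' slice index and the in-plane spacing. Label volumes yield
#' `vm_label_slice` objects; intensity volumes yield plain matrices with
#' attributes `slice_index` and `in_plane_spacing`.
#'
#' @param vol A `vm_label_volume` or `vm_intensity_volume`.
#' @param indices 1-based axial indices (e.g. a `vm_slice_window`'s `indices`).
#' @return List of slices, one per index.
#' @export
extract_slices <- function(vol, indices) {
  stopifnot(inherits(vol, "vm_volume"))
  if (inherits(indices, "vm_slice_window")) indices <- indices$indices
  indices <- as.integer(indices)
  depth <- dim(vol$data)[3]
  if (length(indices) && (min(indices) < 1L || max(indices) > depth))
    stop("slice index out of range", call. = FALSE)
  lapply(indices, function(k) {
    plane <- vol$data[, , k]
    if (is_label_volume(vol)) {
      new_label_slice(plane, vol$spacing[1:2], slice_index = k,
                      label_set = vol$label_set)
    } else {
      structure(plane, slice_index = k, in_plane_spacing = vol$spacing[1:2])
    }
  })
}

#' Pick the measurement window of a simplified mask in one call
#'
#' Convenience composition: area profile, center selection, and window
#' construction.
#'
#' @inheritParams dgm_area_profile
#' @inheritParams select_window
#' @return A `vm_slice_window`.
#' @export
select_measurement_window <- function(mask, half_width = 12L) {
  profile <- dgm_area_profile(mask)
  center <- select_center_slice(profile)
  select_window(center, half_width, depth = dim(mask$data)[3])
}
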