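#' Default label simplification map for 7-tissue fetal masks
#'
#' Multi-class fetal brain tissue masks (FeTA convention: 1 external CSF,
#' 2 gray matter, 3 white matter, 4 ventricular system, 5 cerebellum,
#' 6 deep gray matter, 7 brainstem) are collapsed to the three classes the
#' measurement pipeline needs: 0 background, 1 lateral ventricles, 2 deep
#' gray matter. Every tissue that is neither ventricle nor deep gray matter
#' maps to background.
#'
#' @return Named integer vector: names are original labels, values in `0:2`.
#' @export
#' @examples
#' feta_label_map()
feta_label_map <- function() {
  c("0" = 0L, "1" = 0L, "2" = 0L, "3" = 0L,
    "4" = 1L, "5" = 0L, "6" = 2L, "7" = 0L)
}

validate_label_map <- function(map) {
  map <- stats::setNames(as.integer(map), names(map))
  if (is.null(names(map)) || any(names(map) == ""))
    stop("label map must be a named vector (original label -> simplified label)",
         call. = FALSE)
  if (!all(map %in% 0:2))
    stop("label map targets must lie in {0, 1, 2}", call. = FALSE)
  if (anyDuplicated(names(map)))
    stop("label map assigns an original label more than once", call. = FALSE)
  map
}

#' Simplify a multi-class tissue mask to background / ventricles / deep gray matter
#'
#' Applies a label map to every voxel. Voxel counts are conserved per class:
#' the number of output label-1 voxels equals the number of input voxels whose
#' original label maps to 1. Idempotent on already-simplified masks under the
#' default map.
#'
#' @param mask A `vm_label_volume` (or `vm_label_slice`).
#' @param map Named integer vector, original label -> simplified label in
#'   `{0, 1, 2}`; default [feta_label_map()].
#' @return A simplified object of the same class with `label_set = 0:2`.
#' @export
remap_labels <- function(mask, map = feta_label_map()) {
  map <- validate_label_map(map)
  data <- mask$data
  present <- sort(unique(as.vector(data)))
  unmapped <- setdiff(as.character(present), names(map))
  if (length(unmapped))
    stop("mask contains label(s) missing from the map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  out <- map[as.character(data)]
  if (inherits(mask, "vm_label_slice")) {
    new_label_slice(matrix(out, nrow = nrow(data)), mask$in_plane_spacing,
                    slice_index = mask$slice_index, label_set = 0:2)
  } else {
    new_label_volume(array(out, dim = dim(data)), mask$spacing, label_set = 0:2)
  }
}

is_simplified <- function(mask) all(mask$data %in% 0:2)

#' Per-volume intensity normalization
#'
#' Clips intensities beyond the `clip_lo_pct`/`clip_hi_pct` percentiles, then
#' z-scores the whole volume (mean 0, sd 1 over all voxels). A zero-variance
#' volume maps to all zeros rather than erroring, so constant phantom
#' backgrounds pass through. The result is invariant to positive affine
#' rescaling of the input.
#'
#' @param vol A `vm_intensity_volume`.
#' @param clip_lo_pct,clip_hi_pct Clipping percentiles (0..100).
#' @return A normalized `vm_intensity_volume`.
#' @export
normalize_intensity <- function(vol, clip_lo_pct = 0.5, clip_hi_pct = 99.5) {
  stopifnot(inherits(vol, "vm_intensity_volume"))
  if (length(vol$data) == 0L) stop("empty volume", call. = FALSE)
  if (clip_lo_pct < 0 || clip_hi_pct > 100 || clip_lo_pct >= clip_hi_pct)
    stop("invalid clipping percentiles", call. = FALSE)
  x <- as.vector(vol$data)
  bounds <- stats::quantile(x, c(clip_lo_pct, clip_hi_pct) / 100,
                            names = FALSE, type = 7)
  x <- pmin(pmax(x, bounds[1]), bounds[2])
  s <- stats::sd(x)
  x <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  new_intensity_volume(array(x, dim = dim(vol$data)), vol$spacing)
}

# separable linear interpolation along one array axis at target center positions
interp_axis_linear <- function(arr, axis, old_spacing, new_n, new_spacing) {
  old_n <- dim(arr)[axis]
  # voxel-center coordinates, 0-based grid: (i - 0.5) * spacing
  pos <- (seq_len(new_n) - 0.5) * new_spacing
  src <- pos / old_spacing + 0.5          # fractional index into old grid
  src <- pmin(pmax(src, 1), old_n)
  lo <- floor(src); hi <- pmin(lo + 1, old_n)
  w <- src - lo
  idx_lo <- slice_index_call(arr, axis, lo)
  idx_hi <- slice_index_call(arr, axis, hi)
  wshape <- rep(1L, length(dim(arr))); wshape[axis] <- new_n
  warr <- array(rep(w, each = prod(dim(arr)[seq_len(axis - 1)])),
                dim = replace(dim(idx_lo), axis, new_n))
  idx_lo * (1 - warr) + idx_hi * warr
}

slice_index_call <- function(arr, axis, idx) {
  args <- rep(list(quote(expr = )), length(dim(arr)))
  args[[axis]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

#' Resample a volume to a target voxel spacing
#'
#' Nearest-neighbor for label volumes (so no interpolated labels appear) and
#' trilinear interpolation for intensity volumes. The output grid size is
#' chosen so the physical extent is preserved to within one voxel.
#'
#' @param vol A `vm_intensity_volume` or `vm_label_volume`.
#' @param target_spacing New spacing `(dx, dy, dz)` in mm (a scalar is
#'   recycled isotropically).
#' @return A resampled volume of the same class.
#' @export
resample_to_spacing <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "vm_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target spacing must be positive", call. = FALSE)
  old_spacing <- vol$spacing
  old_dim <- dim(vol$data)
  if (isTRUE(all.equal(old_spacing, target_spacing))) return(vol)
  new_dim <- pmax(1L, as.integer(round(old_dim * old_spacing / target_spacing)))
  if (is_label_volume(vol)) {
    nn_index <- function(axis) {
      pos <- (seq_len(new_dim[axis]) - 0.5) * target_spacing[axis]
      pmin(pmax(ceiling(pos / old_spacing[axis]), 1L), old_dim[axis])
    }
    out <- vol$data[nn_index(1), nn_index(2), nn_index(3), drop = FALSE]
    new_label_volume(array(out, dim = new_dim), target_spacing,
                     label_set = vol$label_set)
  } else {
    out <- vol$data
    for (axis in 1:3)
      out <- interp_axis_linear(out, axis, old_spacing[axis],
                                new_dim[axis], target_spacing[axis])
    new_intensity_volume(out, target_spacing)
  }
}
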