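#' @title Volume and slice containers
#' @description
#' The pipeline works on three lightweight S3 containers: `vm_intensity_volume`
#' (a 3D scalar grid with voxel spacing in mm), `vm_label_volume` (a 3D integer
#' grid with voxel spacing and a permitted label set), and `vm_label_slice`
#' (a 2D integer grid with in-plane spacing and its axial slice index).
#' Array axis 3 is always the axial (slice) axis; axes 1 and 2 are the in-plane
#' left-right and anterior-posterior axes after canonical (RAS) reorientation.
#' Slice indices are 1-based, following R convention.
#' @name vm-volumes
NULL

new_intensity_volume <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm per voxel)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("intensity volume contains non-finite values (NaN/Inf)", call. = FALSE)
  structure(list(data = data, spacing = spacing),
            class = c("vm_intensity_volume", "vm_volume"))
}

new_label_volume <- function(data, spacing, label_set = 0:2) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm per voxel)", call. = FALSE)
  label_set <- sort(unique(as.integer(label_set)))
  if (!is.integer(data)) {
    rounded <- round(data)
    if (any(abs(data - rounded) > 1e-3, na.rm = TRUE))
      stop("label volume contains non-integer values beyond rounding tolerance 1e-3",
           call. = FALSE)
    data <- array(as.integer(rounded), dim = dim(data))
  }
  if (any(!is.finite(data)))
    stop("label volume contains non-finite values", call. = FALSE)
  present <- sort(unique(as.vector(data)))
  bad <- setdiff(present, label_set)
  if (length(bad))
    stop("label volume contains values outside its label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(data = data, spacing = spacing, label_set = label_set),
            class = c("vm_label_volume", "vm_volume"))
}

new_label_slice <- function(data, in_plane_spacing, slice_index = 1L,
                            label_set = 0:2) {
  stopifnot(is.matrix(data))
  in_plane_spacing <- as.numeric(in_plane_spacing)
  if (length(in_plane_spacing) != 2L || any(in_plane_spacing <= 0))
    stop("in-plane spacing must be two strictly positive values (mm)", call. = FALSE)
  slice_index <- as.integer(slice_index)
  if (slice_index < 1L) stop("slice_index must be >= 1", call. = FALSE)
  label_set <- sort(unique(as.integer(label_set)))
  if (!is.integer(data)) {
    rounded <- round(data)
    if (any(abs(data - rounded) > 1e-3))
      stop("label slice contains non-integer values", call. = FALSE)
    data <- matrix(as.integer(rounded), nrow = nrow(data))
  }
  bad <- setdiff(sort(unique(as.vector(data))), label_set)
  if (length(bad))
    stop("label slice contains values outside its label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(data = data, in_plane_spacing = in_plane_spacing,
                 slice_index = slice_index, label_set = label_set),
            class = "vm_label_slice")
}

is_label_volume <- function(x) inherits(x, "vm_label_volume")

#' @export
print.vm_volume <- function(x, ...) {
  kind <- if (is_label_volume(x)) "label" else "intensity"
  cat(sprintf("<fetalvm %s volume> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  if (is_label_volume(x))
    cat("  labels present:", paste(sort(unique(as.vector(x$data))), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.vm_label_slice <- function(x, ...) {
  cat(sprintf("<fetalvm label slice> %d x %d pixels, spacing %s mm, slice %d\n",
              nrow(x$data), ncol(x$data),
              paste(format(x$in_plane_spacing), collapse = " x "), x$slice_index))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into an intensity or label volume. Voxel spacing is
#' taken from the header. When an sform/qform is present the grid is reoriented
#' to the canonical RAS convention so that array axis 3 is the axial axis used
#' by slice selection. In label mode, voxel values are rounded to integers
#' (tolerance 1e-3) and validated against `label_set`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as_labels Read as a label volume (`TRUE`) or intensity volume.
#' @param label_set Permitted integer labels when `as_labels = TRUE`.
#' @return A `vm_intensity_volume` or `vm_label_volume`.
#' @seealso [write_nifti()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' v <- new_label_volume_from_array(array(0L, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' write_nifti(v, f)
#' read_nifti(f, as_labels = TRUE)
read_nifti <- function(path, as_labels = FALSE, label_set = 0:7) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  # reorient to RAS only when the header carries an orientation
  if ((hdr$qform_code > 0 || hdr$sform_code > 0) &&
      !identical(RNifti::orientation(img), "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(spacing <= 0))
    stop("non-positive voxel spacing in NIfTI header", call. = FALSE)
  arr <- as.array(img)
  dims <- dim(arr)
  if (length(dims) > 3L) {
    if (prod(dims[-(1:3)]) != 1L)
      stop("only 3D volumes are supported", call. = FALSE)
    arr <- array(arr, dim = dims[1:3])
  } else if (length(dims) == 2L) {
    arr <- array(arr, dim = c(dims, 1L))
  }
  attributes(arr) <- list(dim = dim(arr))
  if (as_labels) new_label_volume(arr, spacing, label_set = label_set)
  else new_intensity_volume(arr, spacing)
}

#' Write a volume to NIfTI
#'
#' Round trips are lossless for integer label grids; spacing is preserved in
#' the header. Existing files are overwritten.
#'
#' @param volume A `vm_intensity_volume` or `vm_label_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "vm_volume"))
  data <- volume$data
  if (is_label_volume(volume))
    storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct volumes from plain arrays
#'
#' Convenience constructors wrapping validation of the spacing and label-set
#' invariants.
#'
#' @param data 3D array (integer-valued for labels).
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @param label_set Permitted integer labels.
#' @return A `vm_label_volume` / `vm_intensity_volume`.
#' @export
new_label_volume_from_array <- function(data, spacing, label_set = 0:7) {
  new_label_volume(data, spacing, label_set = label_set)
}

#' @rdname new_label_volume_from_array
#' @export
new_intensity_volume_from_array <- function(data, spacing) {
  new_intensity_volume(data, spacing)
}

#' Read a 2D label slice from an 8-bit grayscale PNG
#'
#' PNG carries no physical units, so the caller must supply the in-plane pixel
#' spacing. Pixel values (0..255) are mapped to labels through `palette`, a
#' named map from stored pixel value to label; the default identity palette
#' covers the simplified scheme 0 = background, 1 = ventricles, 2 = deep gray
#' matter. Pixel values absent from the palette are an error, as is RGB input.
#'
#' @param path PNG file path.
#' @param in_plane_spacing Pixel spacing `(dx, dy)` in mm. Required.
#' @param palette Named integer vector: names are stored pixel values,
#'   values are labels.
#' @param slice_index Axial index to record on the slice (1-based).
#' @return A `vm_label_slice`.
#' @seealso [write_label_png()]
#' @export
read_label_png <- function(path, in_plane_spacing,
                           palette = c("0" = 0L, "1" = 1L, "2" = 2L),
                           slice_index = 1L) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (missing(in_plane_spacing) || is.null(in_plane_spacing))
    stop("in_plane_spacing is required: PNG carries no physical units", call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    chan <- dim(img)[3]
    # accept an RGB/RGBA file only if it is actually grayscale
    if (chan >= 3L && !all(img[, , 1] == img[, , 2] & img[, , 2] == img[, , 3]))
      stop("RGB PNG input is not supported without a grayscale-equivalent image",
           call. = FALSE)
    img <- img[, , 1]
  }
  raw_vals <- round(img * 255)
  # readPNG returns row = y; transpose so axis 1 is x (left-right)
  raw_vals <- t(raw_vals)
  lut <- palette
  found <- sort(unique(as.vector(raw_vals)))
  missing_vals <- setdiff(as.character(found), names(lut))
  if (length(missing_vals))
    stop("PNG pixel value(s) with no palette entry: ",
         paste(missing_vals, collapse = ", "), call. = FALSE)
  labels <- matrix(as.integer(lut[as.character(raw_vals)]), nrow = nrow(raw_vals))
  new_label_slice(labels, in_plane_spacing, slice_index = slice_index,
                  label_set = unique(as.integer(lut)))
}

#' Write a label slice as an 8-bit grayscale PNG
#'
#' The inverse of [read_label_png()]: labels are stored through the inverse of
#' `palette` (label -> pixel value).
#'
#' @inheritParams read_label_png
#' @param slice A `vm_label_slice`.
#' @return The path, invisibly.
#' @export
write_label_png <- function(slice, path,
                            palette = c("0" = 0L, "1" = 1L, "2" = 2L)) {
  stopifnot(inherits(slice, "vm_label_slice"))
  inv <- stats::setNames(as.integer(names(palette)), as.character(palette))
  vals <- inv[as.character(slice$data)]
  if (any(is.na(vals)))
    stop("label value with no palette entry", call. = FALSE)
  img <- matrix(vals / 255, nrow = nrow(slice$data))
  png::writePNG(t(img), target = path)
  invisible(path)
}
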