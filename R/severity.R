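#' Clinical severity thresholds for ventriculomegaly
#'
#' Ventriculomegaly (VM) is diagnosed at an atrial width of 10 mm or more and
#' graded by width: mild (10 to 12.5 mm), moderate (12.5 to 15 mm) and severe
#' (15 mm and above). Intervals are half-open and lower-inclusive, so each
#' threshold value belongs to the class it opens (10.0 is Mild, 12.5 is
#' Moderate, 15.0 is Severe).
#'
#' @param vm_min Diagnostic threshold in mm (default 10).
#' @param moderate_min Moderate threshold in mm (default 12.5).
#' @param severe_min Severe threshold in mm (default 15).
#' @return A `vm_thresholds` list.
#' @export
severity_thresholds <- function(vm_min = 10, moderate_min = 12.5,
                                severe_min = 15) {
  if (!(vm_min > 0 && vm_min < moderate_min && moderate_min < severe_min))
    stop("thresholds must satisfy 0 < vm_min < moderate_min < severe_min",
         call. = FALSE)
  structure(list(vm_min = vm_min, moderate_min = moderate_min,
                 severe_min = severe_min),
            class = "vm_thresholds")
}

#' Ordinal severity classes
#'
#' @return Character vector of the four class names in increasing severity.
#' @export
severity_classes <- function() c("Normal", "Mild", "Moderate", "Severe")

#' Map ventricular width to a severity class
#'
#' Vectorized over `width_mm`. Classes are assigned by half-open,
#' lower-inclusive intervals: Normal below `vm_min`, Mild in
#' `[vm_min, moderate_min)`, Moderate in `[moderate_min, severe_min)`,
#' Severe at `severe_min` and above.
#'
#' @param width_mm Numeric vector of widths in mm (must be >= 0).
#' @param thresholds A `vm_thresholds` (default [severity_thresholds()]).
#' @return Ordered factor with levels Normal < Mild < Moderate < Severe and
#'   attribute `thresholds`.
#' @export
#' @examples
#' severity_from_width(c(8, 10, 13.2, 15))
severity_from_width <- function(width_mm, thresholds = severity_thresholds()) {
  stopifnot(inherits(thresholds, "vm_thresholds"))
  width_mm <- as.numeric(width_mm)
  if (any(!is.finite(width_mm)) || any(width_mm < 0))
    stop("widths must be finite and >= 0", call. = FALSE)
  cls <- cut(width_mm,
             breaks = c(-Inf, thresholds$vm_min, thresholds$moderate_min,
                        thresholds$severe_min, Inf),
             labels = severity_classes(),
             right = FALSE, ordered_result = TRUE)
  attr(cls, "thresholds") <- thresholds
  cls
}

#' Attach a severity label to a measurement
#'
#' Builds one labeled record from a `vm_measurement`: per-side widths, final
#' width, ventricular volume and the severity class of the final width.
#' Volume is carried through as a reported marker but does not enter the
#' class decision, which is width-based.
#'
#' @param measurement A `vm_measurement`.
#' @param thresholds A `vm_thresholds`.
#' @param case_id Identifier for the case (default `NA`).
#' @return One-row tibble: `case_id`, `left_width_mm`, `right_width_mm`,
#'   `width_mm`, `volume_cm3`, `slice_index`, `split_method`, `class`.
#' @export
label_case <- function(measurement, thresholds = severity_thresholds(),
                       case_id = NA_character_) {
  stopifnot(inherits(measurement, "vm_measurement"))
  cls <- severity_from_width(measurement$final_width_mm, thresholds)
  tibble::tibble(case_id = as.character(case_id),
                 left_width_mm = measurement$left_width_mm,
                 right_width_mm = measurement$right_width_mm,
                 width_mm = measurement$final_width_mm,
                 volume_cm3 = measurement$volume_cm3,
                 slice_index = measurement$slice_index,
                 split_method = measurement$split_method,
                 class = as.character(cls))
}
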