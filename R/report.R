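#' Structured prompt for a measured, labeled case
#'
#' Formats a labeled measurement into the fixed template used to brief an
#' explanation model (or a reader):
#' `Slice: [Image]; Severity: <class> VM; Width: <w> mm; Volume: <v> cm^3`,
#' with width and volume printed to one decimal. The template is injective
#' over (class, width, volume) at that precision and is exactly invertible by
#' [parse_prompt()].
#'
#' @param measurement A `vm_measurement` (or anything with `final_width_mm`
#'   and `volume_cm3`).
#' @param label Severity class: a factor/character from
#'   [severity_from_width()].
#' @return The prompt string.
#' @export
#' @examples
#' m <- list(final_width_mm = 13.2, volume_cm3 = 3.6)
#' build_prompt(m, "Moderate")
build_prompt <- function(measurement, label) {
  label <- as.character(label)
  stopifnot(length(label) == 1L, label %in% severity_classes())
  sprintf("Slice: [Image]; Severity: %s VM; Width: %.1f mm; Volume: %.1f cm^3",
          label, measurement$final_width_mm, measurement$volume_cm3)
}

#' Parse a structured prompt back into its fields
#'
#' @param prompt_text A string produced by [build_prompt()].
#' @return List with `class`, `width_mm`, `volume_cm3`.
#' @export
parse_prompt <- function(prompt_text) {
  pattern <- "^Slice: \\[Image\\]; Severity: (\\w+) VM; Width: ([-0-9.]+) mm; Volume: ([-0-9.]+) cm\\^3$"
  m <- regmatches(prompt_text, regexec(pattern, prompt_text))[[1]]
  if (length(m) != 4L) stop("not a recognized prompt", call. = FALSE)
  list(class = m[2], width_mm = as.numeric(m[3]), volume_cm3 = as.numeric(m[4]))
}

#' Offline templated explanation of a severity label
#'
#' Generates a short clinical explanation without any external service,
#' citing only the measured width, volume, and the threshold the width
#' crossed (or stayed below). Widths within `borderline_mm` of any threshold
#' are flagged as borderline, since interpretation is least certain near
#' class boundaries. The text never contains a numeric value other than the
#' measurement's width/volume and the configured thresholds.
#'
#' @param measurement A `vm_measurement` (or list with `final_width_mm`,
#'   `volume_cm3`).
#' @param label Severity class for the measurement.
#' @param thresholds A `vm_thresholds`.
#' @param borderline_mm Half-width of the borderline window around each
#'   threshold (default 0.5 mm).
#' @return Explanation string.
#' @export
render_offline_explanation <- function(measurement, label,
                                       thresholds = severity_thresholds(),
                                       borderline_mm = 0.5) {
  label <- as.character(label)
  stopifnot(label %in% severity_classes(), inherits(thresholds, "vm_thresholds"))
  w <- measurement$final_width_mm
  v <- measurement$volume_cm3
  fmt <- function(x) formatC(x, format = "fg")
  core <- switch(label,
    Normal = sprintf(
      "The lateral ventricles measure %.1f mm, below the %s mm diagnostic threshold; no ventriculomegaly.",
      w, fmt(thresholds$vm_min)),
    Mild = sprintf(
      "The lateral ventricles measure %.1f mm, at or above the %s mm threshold but below %s mm, indicating mild ventriculomegaly.",
      w, fmt(thresholds$vm_min), fmt(thresholds$moderate_min)),
    Moderate = sprintf(
      "The lateral ventricles exceed the %s mm threshold, measuring %.1f mm, indicating moderate ventriculomegaly.",
      fmt(thresholds$moderate_min), w),
    Severe = sprintf(
      "The lateral ventricles measure %.1f mm, at or above the %s mm threshold, indicating severe ventriculomegaly.",
      w, fmt(thresholds$severe_min)))
  if (!is.null(v) && !is.na(v)) {
    core <- paste(core, sprintf("Ventricular volume is %.1f cm^3.", v))
    if (label != "Normal")
      core <- paste(core, "Volume supports abnormal fluid accumulation.")
  }
  cuts <- unlist(thresholds)
  if (any(abs(w - cuts) < borderline_mm))
    core <- paste(core,
                  "Borderline: the width lies close to a severity threshold and should be interpreted with caution.")
  core
}

#' Assemble a full case report
#'
#' Bundles the measurement, its severity label, the structured prompt and the
#' offline explanation into one record. An external language-model adapter
#' can be plugged in via `explainer`, a function `(prompt_text) -> character`;
#' the default is the offline template, so no network access is ever needed.
#'
#' @param measurement A `vm_measurement`.
#' @param thresholds A `vm_thresholds`.
#' @param case_id Case identifier.
#' @param explainer `NULL` for the offline template, or a function mapping
#'   the prompt text to an explanation string.
#' @return A `vm_case_report`: list with `case_id`, `class`, `width_mm`,
#'   `volume_cm3`, `prompt_text`, `explanation_text`.
#' @export
build_case_report <- function(measurement, thresholds = severity_thresholds(),
                              case_id = NA_character_, explainer = NULL) {
  stopifnot(inherits(measurement, "vm_measurement"))
  cls <- as.character(severity_from_width(measurement$final_width_mm, thresholds))
  prompt <- build_prompt(measurement, cls)
  explanation <- if (is.null(explainer)) {
    render_offline_explanation(measurement, cls, thresholds)
  } else {
    explainer(prompt)
  }
  structure(list(case_id = as.character(case_id), class = cls,
                 width_mm = measurement$final_width_mm,
                 volume_cm3 = measurement$volume_cm3,
                 prompt_text = prompt, explanation_text = explanation),
            class = "vm_case_report")
}

#' @export
print.vm_case_report <- function(x, ...) {
  cat("<fetalvm case report>", if (!is.na(x$case_id)) x$case_id, "\n")
  cat(" ", x$prompt_text, "\n")
  cat(" ", x$explanation_text, "\n")
  invisible(x)
}
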