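#' Pipeline configuration
#'
#' Validated bag of the tunable parameters shared by the analysis entry
#' points and the CLI. Unknown keys are rejected so a typo in a YAML config
#' cannot silently fall back to a default.
#'
#' @param label_map Named map original label -> simplified label
#'   ([feta_label_map()] by default).
#' @param thresholds A `vm_thresholds`.
#' @param half_width Slice-window half width (default 12, a 25-slice stack).
#' @param width_convention `"short_side"` or `"long_side"`.
#' @param split_axis `"x"` or `"y"`.
#' @param png_spacing In-plane spacing assumed for PNG input, mm (default
#'   0.5 isotropic, typical of reconstructed fetal T2-weighted MRI).
#' @param clip_percentiles Intensity clipping percentiles.
#' @param target_spacing Optional resampling target in mm (`NULL` = keep
#'   native spacing).
#' @param seed Integer seed used by phantom generation.
#' @return A `vm_config` list.
#' @export
vm_config <- function(label_map = feta_label_map(),
                      thresholds = severity_thresholds(),
                      half_width = 12L,
                      width_convention = c("short_side", "long_side"),
                      split_axis = c("x", "y"),
                      png_spacing = c(0.5, 0.5),
                      clip_percentiles = c(0.5, 99.5),
                      target_spacing = NULL,
                      seed = 1L) {
  width_convention <- match.arg(width_convention)
  split_axis <- match.arg(split_axis)
  label_map <- validate_label_map(label_map)
  stopifnot(inherits(thresholds, "vm_thresholds"),
            half_width >= 0, length(png_spacing) == 2L, all(png_spacing > 0),
            length(clip_percentiles) == 2L,
            clip_percentiles[1] < clip_percentiles[2])
  if (!is.null(target_spacing) && any(target_spacing <= 0))
    stop("target_spacing must be positive", call. = FALSE)
  structure(list(label_map = label_map, thresholds = thresholds,
                 half_width = as.integer(half_width),
                 width_convention = width_convention,
                 split_axis = split_axis,
                 png_spacing = as.numeric(png_spacing),
                 clip_percentiles = as.numeric(clip_percentiles),
                 target_spacing = target_spacing,
                 seed = as.integer(seed)),
            class = "vm_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `label_map` (map), `thresholds` (map with `vm_min`,
#' `moderate_min`, `severe_min`), `half_width`, `width_convention`,
#' `split_axis`, `png_spacing`, `clip_percentiles`, `target_spacing`, `seed`.
#' Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `vm_config`.
#' @export
read_vm_config <- function(path) {
  if (!file.exists(path)) stop_vm_input(paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("label_map", "thresholds", "half_width", "width_convention",
             "split_axis", "png_spacing", "clip_percentiles",
             "target_spacing", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_vm_input(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  args <- raw
  if (!is.null(raw$label_map))
    args$label_map <- unlist(raw$label_map)
  if (!is.null(raw$thresholds))
    args$thresholds <- do.call(severity_thresholds, raw$thresholds)
  do.call(vm_config, args)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config)[order(names(config))], f)
  unname(tools::md5sum(f))
}

prepare_mask <- function(mask, config) {
  if (!is.null(config$target_spacing) && is_label_volume(mask))
    mask <- resample_to_spacing(mask, config$target_spacing)
  if (!is_simplified(mask)) mask <- remap_labels(mask, config$label_map)
  mask
}

#' Analyze one case (2D or 3D)
#'
#' The end-to-end single-case pipeline. For 3D NIfTI masks: simplify the
#' labels, select the axial measurement plane by maximal deep-gray-matter
#' area, split/measure the ventricles on that plane, compute the total
#' ventricular volume, grade severity, and build the case report. For 2D
#' input (PNG label slice, or a single-slice NIfTI) the slice-selection stage
#' is skipped and volume is not defined (reported as `NA`).
#'
#' When `output_dir` is given, writes `<case>_measurement.json`,
#' `<case>_label.csv` and `<case>_report.txt`.
#'
#' @param input Path to a NIfTI mask (`.nii`/`.nii.gz`) or a label PNG.
#' @param mode `"3d"` or `"2d"`. PNG input implies `"2d"`.
#' @param config A `vm_config`.
#' @param output_dir Optional output directory.
#' @param case_id Case identifier (default: input file name).
#' @return Invisibly, a list with `measurement`, `label` (one-row tibble) and
#'   `report`.
#' @export
vm_analyze <- function(input, mode = c("3d", "2d"), config = vm_config(),
                       output_dir = NULL, case_id = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(input)) stop_vm_input(paste("input not found:", input))
  if (is.null(case_id))
    case_id <- sub("\\.(nii(\\.gz)?|png)$", "", basename(input))
  is_png <- grepl("\\.png$", input, ignore.case = TRUE)
  if (is_png && mode == "3d")
    stop_vm_input("PNG input requires mode '2d'")

  if (is_png) {
    slice <- read_label_png(input, in_plane_spacing = config$png_spacing)
    if (!all(slice$data %in% 0:2))
      slice <- remap_labels(slice, config$label_map)
    if (!any(slice$data == 1L))
      stop_vm_anatomy("no ventricle pixels in input slice")
    measurement <- measure_slice(slice, convention = config$width_convention,
                                 split_axis = config$split_axis)
  } else {
    mask <- tryCatch(read_nifti(input, as_labels = TRUE),
                     error = function(e) stop_vm_input(conditionMessage(e)))
    mask <- prepare_mask(mask, config)
    if (mode == "2d" || dim(mask$data)[3] == 1L) {
      plane <- extract_slices(mask, 1L)[[1]]
      if (!any(plane$data == 1L))
        stop_vm_anatomy("no ventricle pixels in input slice")
      measurement <- measure_slice(plane, convention = config$width_convention,
                                   split_axis = config$split_axis)
    } else {
      measurement <- measure_volume(mask, convention = config$width_convention,
                                    split_axis = config$split_axis)
    }
  }
  labeled <- label_case(measurement, config$thresholds, case_id = case_id)
  report <- build_case_report(measurement, config$thresholds, case_id = case_id)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      c(list(case_id = case_id), unclass(measurement),
        list(class = report$class)),
      file.path(output_dir, paste0(case_id, "_measurement.json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.csv(labeled,
                     file.path(output_dir, paste0(case_id, "_label.csv")),
                     row.names = FALSE)
    writeLines(c(report$prompt_text, report$explanation_text),
               file.path(output_dir, paste0(case_id, "_report.txt")))
  }
  invisible(list(measurement = measurement, label = labeled, report = report))
}

#' Label a directory of segmentation masks
#'
#' Measures and grades every NIfTI mask in a directory (sorted by file name,
#' so the output ordering is deterministic), collecting one labeled row per
#' case. Unreadable or anatomically deficient cases are skipped with a
#' warning and recorded in the run log rather than aborting the batch.
#'
#' Writes `labels.csv` and `run_log.txt` (configuration hash, package
#' version, per-case outcome) when `output_dir` is given, and prints the
#' class distribution.
#'
#' @param input_dir Directory containing `.nii`/`.nii.gz` masks.
#' @param config A `vm_config`.
#' @param output_dir Optional output directory.
#' @param quiet Suppress the class-count printout.
#' @return Tibble of labeled cases (possibly zero rows).
#' @export
vm_label_cohort <- function(input_dir, config = vm_config(),
                            output_dir = NULL, quiet = FALSE) {
  if (!dir.exists(input_dir)) stop_vm_input(paste("not a directory:", input_dir))
  files <- sort(list.files(input_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  log_lines <- c(sprintf("fetalvm %s", as.character(utils::packageVersion("fetalvm"))),
                 sprintf("config_hash %s", config_hash(config)),
                 sprintf("n_inputs %d", length(files)))
  rows <- list()
  for (f in files) {
    # reader warnings on malformed files precede the error; keep the log entry
    res <- tryCatch(suppressWarnings(vm_analyze(f, mode = "3d", config = config)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", basename(f), ": ", conditionMessage(res),
              call. = FALSE)
      log_lines <- c(log_lines,
                     sprintf("SKIP %s %s", basename(f), conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res$label
      log_lines <- c(log_lines,
                     sprintf("OK %s width=%.3f class=%s", basename(f),
                             res$label$width_mm, res$label$class))
    }
  }
  labels <- if (length(rows)) do.call(rbind, rows) else
    label_case(new_vm_measurement(0, 0, NA_real_, NA_integer_, NA_character_))[0, ]
  if (length(files) == 0L)
    warning("no NIfTI masks found in ", input_dir, call. = FALSE)
  if (!quiet && nrow(labels)) {
    cat("class distribution:\n")
    print(table(factor(labels$class, levels = severity_classes())))
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(labels, file.path(output_dir, "labels.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  }
  labels
}

#' Write a phantom cohort to disk
#'
#' Generates a cohort with [generate_cohort()] and writes, per phantom, the
#' intensity and label NIfTI volumes plus one `truth.csv` ground-truth table.
#'
#' @param n Number of phantoms.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param width_range Per-side width range in mm.
#' @return The truth tibble, invisibly.
#' @export
vm_phantom_cohort <- function(n, out_dir, seed = 1L, width_range = c(6, 20)) {
  cohort <- generate_cohort(n, width_range = width_range, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$phantoms)) {
    ph <- cohort$phantoms[[i]]
    id <- cohort$truth$case_id[i]
    write_nifti(ph$label, file.path(out_dir, paste0(id, "_mask.nii.gz")))
    write_nifti(ph$intensity, file.path(out_dir, paste0(id, "_T2w.nii.gz")))
  }
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(cohort$truth)
}
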