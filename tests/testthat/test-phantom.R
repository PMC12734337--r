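test_that("phantom construction fixes truth width, center slice, and class", {
  ph <- generate_phantom(phantom_spec(left_width_mm = 13, right_width_mm = 11,
                                      separation_gap_mm = 4,
                                      dgm_peak_slice = 30))
  expect_equal(ph$truth$true_final_width_mm, 13)
  expect_identical(ph$truth$true_center_slice, 30L)
  expect_identical(ph$truth$true_class, "Moderate")
  expect_equal(ph$truth$true_final_width_mm,
               max(ph$truth$true_left_width_mm, ph$truth$true_right_width_mm))

  # the label volume satisfies its invariants and holds all three classes
  expect_true(all(ph$label$data %in% 0:2))
  expect_true(all(c(1L, 2L) %in% ph$label$data))
  expect_identical(dim(ph$intensity$data), dim(ph$label$data))
})

test_that("generated transverse extent matches the requested width to one voxel", {
  ph <- generate_phantom(phantom_spec(left_width_mm = 13, right_width_mm = 11,
                                      dgm_peak_slice = 30))
  sl <- ph$label$data[, , 30]
  # exhaustive scan: columns spanned by the left blob (left of the midline)
  nx <- nrow(sl)
  left_cols <- which(apply(sl[seq_len(nx / 2), ] == 1L, 1, any))
  extent <- (max(left_cols) - min(left_cols) + 1) * ph$label$spacing[1]
  expect_lte(abs(extent - 13), 0.5)
})

test_that("the deep-gray-matter area profile peaks uniquely at the stated slice", {
  for (peak in c(20, 30, 41)) {
    ph <- generate_phantom(phantom_spec(dgm_peak_slice = peak))
    prof <- as.numeric(dgm_area_profile(ph$label))
    expect_identical(which.max(prof), as.integer(peak))
    expect_identical(sum(prof == max(prof)), 1L)
  }
})

test_that("ventricles stay separated by the requested gap at the peak slice", {
  ph <- generate_phantom(phantom_spec(separation_gap_mm = 4, dgm_peak_slice = 30))
  sl <- ph$label$data[, , 30]
  cols <- which(apply(sl == 1L, 1, any))
  gap_cols <- max(diff(cols)) - 1
  expect_gte(gap_cols * ph$label$spacing[1], 4 - 2 * ph$label$spacing[1])
})

test_that("zero-width phantoms have empty ventricle labels and zero truth volume", {
  ph <- generate_phantom(phantom_spec(left_width_mm = 0, right_width_mm = 0))
  expect_false(any(ph$label$data == 1L))
  expect_equal(ph$truth$true_volume_cm3, 0)
  expect_identical(ph$truth$true_class, "Normal")
})

test_that("identical seeds give bit-identical phantoms and cohorts", {
  a <- generate_phantom(phantom_spec(seed = 99))
  b <- generate_phantom(phantom_spec(seed = 99))
  expect_identical(a$label$data, b$label$data)
  expect_identical(a$intensity$data, b$intensity$data)

  c1 <- generate_cohort(3, seed = 17, include_intensity = FALSE)
  c2 <- generate_cohort(3, seed = 17, include_intensity = FALSE)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$phantoms, function(p) p$label$data),
                   lapply(c2$phantoms, function(p) p$label$data))
})

test_that("cohorts span all four severity classes over the clinical width range", {
  co <- generate_cohort(40, width_range = c(6, 20), seed = 5,
                        include_intensity = FALSE)
  expect_identical(nrow(co$truth), 40L)
  expect_setequal(unique(co$truth$true_class), severity_classes())
  # single-phantom cohort works
  expect_identical(nrow(generate_cohort(1, seed = 2,
                                        include_intensity = FALSE)$truth), 1L)
  expect_error(generate_cohort(0), ">= 1")
})

test_that("phantom labels survive a NIfTI round trip losslessly", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(ph$label, f)
  r <- read_nifti(f, as_labels = TRUE)
  expect_identical(r$data, ph$label$data)
  expect_equal(r$spacing, ph$label$spacing, tolerance = 1e-6)
})

test_that("impossible phantom geometry is rejected", {
  expect_error(generate_phantom(phantom_spec(left_width_mm = 40,
                                             right_width_mm = 40)),
               "bounds")
  expect_error(phantom_spec(dgm_peak_slice = 200), "depth")
})
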