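test_that("phantom generation is deterministic and anatomically complete", {
  sp <- phantom_spec(curve_angle_deg = 15, curve_pattern = "single_C",
                     noise_sigma = 0.05, seed = 7)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(unclass(p1$image), unclass(p2$image))
  # all five structures present and brighter than background
  bg <- stats::median(unclass(p1$image)[!Reduce(`|`, p1$masks)])
  for (nm in names(p1$masks)) {
    expect_gt(sum(p1$masks[[nm]]), 0)
    expect_gt(mean(unclass(p1$image)[p1$masks[[nm]]]), bg)
  }
})

test_that("straight noiseless phantom has a constant-column vertical midline", {
  ph <- fix_phantom(0, noise = 0)
  expect_lt(diff(range(ph$truth$true_midline$column)), 1e-9)
  expect_false(is.unsorted(ph$truth$true_midline$row, strictly = TRUE))
})

test_that("ground-truth class follows the 6/10 degree boundaries", {
  expect_equal(as.character(fix_phantom(15)$truth$true_class), "major_gt_10")
  p8 <- generate_phantom(phantom_spec(curve_angle_deg = 8,
                                      curve_pattern = "single_C", seed = 2))
  expect_equal(as.character(p8$truth$true_class), "mild_6_10")
  expect_equal(as.character(fix_phantom(0)$truth$true_class), "none")
})

test_that("true angle matches the analytic tangent range of the midline", {
  for (case in list(c(12, 1), c(25, 2))) {
    for (pat in c("single_C", "double_S")) {
      ph <- generate_phantom(phantom_spec(curve_angle_deg = case[1],
                                          curve_pattern = pat,
                                          noise_sigma = 0, seed = case[2]))
      bm <- ph$truth$body_midline
      theta <- atan(diff(bm$column) / diff(bm$row)) * 180 / pi
      expect_lt(abs(diff(range(theta)) - case[1]), 0.1)
    }
  }
})

test_that("re-measuring the true midline recovers the injected angle", {
  for (ang in c(8, 20, 30)) {
    ph <- fix_phantom(ang)
    m <- measure_curvature(ph$truth$true_midline)
    expect_lt(abs(m$angle_deg - ang), 0.5)
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(curve_angle_deg = 5, curve_pattern = "straight"),
               class = "dxascol_invalid_input")
  expect_error(phantom_spec(curve_angle_deg = 0, curve_pattern = "single_C"),
               class = "dxascol_invalid_input")
  expect_error(phantom_spec(apex_row_fraction = 1),
               class = "dxascol_invalid_input")
  expect_error(generate_phantom(phantom_spec(image_height_px = 50,
                                             image_width_px = 20)),
               class = "dxascol_sizing")
})

test_that("repeat pairs share the spine and are identical at zero jitter", {
  sp <- phantom_spec(curve_angle_deg = 12, curve_pattern = "single_C",
                     noise_sigma = 0, seed = 5)
  pr0 <- generate_repeat_pair(sp, jitter = list(tilt_sd_deg = 0,
                                                offset_sd_px = 0, asym_sd = 0))
  expect_equal(unclass(pr0$scan1$image), unclass(pr0$scan2$image),
               ignore_attr = TRUE)
  prj <- generate_repeat_pair(sp, jitter = list(tilt_sd_deg = 2,
                                                offset_sd_px = 4,
                                                asym_sd = 0.02))
  expect_equal(prj$scan1$truth$true_angle_deg, prj$scan2$truth$true_angle_deg)
  expect_false(identical(unclass(prj$scan1$image), unclass(prj$scan2$image)))
  expect_error(generate_repeat_pair(sp, jitter = list(tilt_sd_deg = -1)),
               class = "dxascol_invalid_input")
})

test_that("cohort prevalence, determinism and degenerate inputs behave", {
  co <- generate_cohort(400, prevalence = 0.059, seed = 3, render = FALSE)
  n_scol <- sum(co$truth$true_class != "none")
  # binomial 99.9% band around 0.059 * 400
  expect_true(abs(n_scol - 400 * 0.059) <
                3.3 * sqrt(400 * 0.059 * 0.941) + 1)
  expect_equal(nrow(co$truth), 400)
  co2 <- generate_cohort(400, prevalence = 0.059, seed = 3, render = FALSE)
  expect_identical(co$truth, co2$truth)
  co0 <- generate_cohort(50, prevalence = 0, seed = 1, render = FALSE)
  expect_true(all(co0$truth$true_class == "none"))
  expect_error(generate_cohort(0), class = "dxascol_empty_cohort")
  # label consistency: class is a pure function of angle
  expect_identical(co$truth$true_class, grade_curve(co$truth$true_angle_deg))
})

test_that("16-bit TIFF round trip preserves the image", {
  ph <- fix_phantom(15, noise = 0.05, seed = 4)
  f <- withr::local_tempfile(fileext = ".tif")
  write_dxa(ph$image, f)
  back <- read_dxa(f)
  expect_equal(dim(back), dim(ph$image))
  expect_lt(max(abs(unclass(back) - unclass(ph$image))), 2^-15)
})
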