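test_that("phantom generation is deterministic and schema-stable", {
  spec <- quarter_phase_spec(noise_sd_contour = 0.05, noise_sd_pressure = 0.2,
                             seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a, b)
  expect_named(a$contours,
               c("frame_index", "t_seconds", "vertex_index", "x_mm", "y_mm"))
  expect_named(a$pressure, c("t_seconds", "p_mmHg"))
  expect_equal(nrow(a$contours), spec$n_frames * spec$contour_points)

  # byte-identical CSV on repeated generation
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_contours_csv(a$contours, f1)
  write_contours_csv(b$contours, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a still phantom (no pulsation, no noise) gives zero strain", {
  spec <- quarter_phase_spec(pressure_amplitude = 0, noise_sd_contour = 0)
  ph <- generate_phantom(spec)
  per_frame <- split(ph$contours[c("x_mm", "y_mm")], ph$contours$frame_index)
  expect_true(all(vapply(per_frame, identical, logical(1), per_frame[[1]])))
  st <- strain_series(ph$contours, "min-pressure", ph$pressure)
  expect_equal(st$epsilon, rep(0, spec$n_frames))
})

test_that("noise-free peak strain matches the analytic construction", {
  for (E in c(10, 80)) {
    spec <- quarter_phase_spec(elastic_modulus_true = E)
    ph <- generate_phantom(spec)
    st <- strain_series(ph$contours, "min-pressure", ph$pressure)
    expect_equal(max(st$epsilon), ph$ground_truth$strain_peak,
                 tolerance = 1e-10)
    expect_equal(ph$ground_truth$strain_peak,
                 2 * spec$pressure_amplitude / E)
  }
})

test_that("invalid phantom specs fail naming the offending field", {
  expect_error(vessel_phantom_spec(baseline_radius = -1), "baseline_radius",
               class = "va_validation_error")
  expect_error(vessel_phantom_spec(n_frames = 3), "n_frames",
               class = "va_validation_error")
  expect_error(vessel_phantom_spec(contour_points = 4), "contour_points",
               class = "va_validation_error")
  expect_error(vessel_phantom_spec(pressure_amplitude = -2),
               "pressure_amplitude", class = "va_validation_error")
  expect_error(generate_phantom(list()), class = "va_validation_error")
})

test_that("zero-variance cohorts reproduce the specified ratios exactly", {
  spec <- cohort_spec(between_animal_cv = 0, measurement_cv = 0, seed = 2)
  coh <- generate_cohort(spec)
  wide <- tidyr::pivot_wider(coh, names_from = "tissue",
                             values_from = "modulus")
  wide$ratio <- wide$itev / wide$native
  by_tp <- dplyr::summarise(dplyr::group_by(wide, timepoint_months),
                            r = unique(ratio), .groups = "drop")
  expect_equal(by_tp$r[match(spec$timepoints, by_tp$timepoint_months)],
               spec$modulus_ratio_means, tolerance = 1e-12)
})

test_that("cohort cardinality and schema follow the spec", {
  coh <- generate_cohort(cohort_spec(n_animals = 7, seed = 3))
  expect_named(coh, c("animal_id", "timepoint_months", "tissue", "modulus"))
  expect_equal(nrow(dplyr::distinct(coh, animal_id, timepoint_months)), 42L)
  expect_equal(nrow(coh), 84L)  # 42 animal x timepoint pairs, two tissues
  expect_setequal(unique(coh$tissue), c("native", "itev"))
  expect_identical(coh, generate_cohort(cohort_spec(n_animals = 7, seed = 3)))
})

test_that("cohort spec validation rejects bad inputs", {
  expect_error(cohort_spec(timepoints = c(1, 2), modulus_ratio_means = c(1, 1)),
               "timepoints", class = "va_validation_error")
  expect_error(cohort_spec(timepoints = c(0, 2, 1),
                           modulus_ratio_means = c(1, 1, 1)),
               class = "va_validation_error")
  expect_error(cohort_spec(modulus_ratio_means = c(1, 2)),
               class = "va_validation_error")
  expect_error(cohort_spec(between_animal_cv = 1.2),
               class = "va_validation_error")
})

test_that("printed degradation series load exactly as published", {
  deg <- load_printed_degradation()
  expect_equal(deg$strength$time_weeks, c(0, 1, 2, 3, 4, 6, 9))
  expect_equal(deg$strength$value, c(9.3, 6.9, 5.3, 2.1, 1.2, 0.4, 0.1))
  expect_equal(deg$mw$time_weeks, c(0, 1, 2, 4, 6, 8, 13, 20, 25))
  expect_equal(deg$mw$value,
               c(194267, 163566, 124383, 82709, 51737, 32867, 8655, 6190,
                 4387))
  # both series are strictly decreasing in time
  expect_true(all(diff(deg$strength$value) < 0))
  expect_true(all(diff(deg$mw$value) < 0))
})
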