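test_that("loop pairing interpolates pressure onto frame times", {
  strain <- tibble::tibble(t_seconds = 0:5, epsilon = (0:5) / 50)
  pressure <- tibble::tibble(t_seconds = seq(-1, 6, by = 0.1),
                             p_mmHg = 10 + seq(-1, 6, by = 0.1))
  loop <- build_ps_loop(strain, pressure)
  expect_equal(nrow(loop), 6)  # one pair per in-overlap frame
  expect_equal(loop$p_mmHg, 10 + (0:5), tolerance = 1e-9)

  # identical timebases: exact pairing, no interpolation error
  p2 <- tibble::tibble(t_seconds = 0:5, p_mmHg = c(3, 1, 4, 1, 5, 9))
  expect_equal(build_ps_loop(strain, p2)$p_mmHg, p2$p_mmHg)

  # partial overlap restricts to the shared window
  p3 <- tibble::tibble(t_seconds = seq(2, 9, 0.5), p_mmHg = 1:15)
  expect_equal(build_ps_loop(strain, p3)$t_seconds, 2:5)
})

test_that("loop construction rejects bad timebases", {
  strain <- tibble::tibble(t_seconds = 0:5, epsilon = (0:5) / 50)
  late <- tibble::tibble(t_seconds = 10:20, p_mmHg = 1:11)
  expect_error(build_ps_loop(strain, late), class = "va_validation_error")
  wobble <- tibble::tibble(t_seconds = c(0, 2, 1, 3), p_mmHg = 1:4)
  expect_error(build_ps_loop(strain, wobble), class = "va_validation_error")
  expect_error(build_ps_loop(strain[1:3, ],
                             tibble::tibble(t_seconds = 0:5, p_mmHg = 0:5)),
               class = "va_validation_error")
})

test_that("a phase lag opens the loop (nonzero enclosed area)", {
  shoelace <- function(x, y) {
    n <- length(x); j <- c(2:n, 1)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }
  ph_lag <- generate_phantom(quarter_phase_spec(hysteresis_phase_lag = 0.4,
                                                seed = 8))
  st <- strain_series(ph_lag$contours, "min-pressure", ph_lag$pressure)
  loop <- build_ps_loop(st, ph_lag$pressure)
  one_cycle <- loop[1:40, ]  # 40 frames per cycle at this spec
  area_lag <- shoelace(one_cycle$epsilon, one_cycle$p_mmHg)

  ph0 <- generate_phantom(quarter_phase_spec(seed = 8))
  st0 <- strain_series(ph0$contours, "min-pressure", ph0$pressure)
  loop0 <- build_ps_loop(st0, ph0$pressure)[1:40, ]
  area0 <- shoelace(loop0$epsilon, loop0$p_mmHg)
  expect_gt(area_lag, 100 * max(area0, 1e-12))
})

test_that("modulus estimators match hand-computed anchors", {
  loop <- tibble::tibble(epsilon = c(0, 0.1, 0.2), p_mmHg = c(5, 10, 15))
  expect_equal(elastic_modulus(loop, "extrema")$E, 50)
  expect_equal(elastic_modulus(loop, "loop-fit")$E, 50)
  expect_error(
    elastic_modulus(tibble::tibble(epsilon = rep(0, 5), p_mmHg = 1:5)),
    class = "va_degenerate_loop")
})

test_that("both estimators recover the generating modulus exactly", {
  spec <- quarter_phase_spec(elastic_modulus_true = 50, seed = 1)
  e_fit <- recover_modulus(spec, "loop-fit")
  e_ext <- recover_modulus(spec, "extrema")
  expect_equal(e_fit, 50, tolerance = 1e-6)
  expect_equal(e_ext, 50, tolerance = 1e-6)
})

test_that("modulus scales linearly in pressure and inversely in strain", {
  ph <- generate_phantom(quarter_phase_spec(hysteresis_phase_lag = 0.3,
                                            noise_sd_contour = 0.02,
                                            seed = 12))
  st <- strain_series(ph$contours, "min-pressure", ph$pressure)
  loop <- build_ps_loop(st, ph$pressure)
  for (m in c("loop-fit", "extrema")) {
    E0 <- elastic_modulus(loop, m)$E
    up <- dplyr::mutate(loop, p_mmHg = p_mmHg * 3)
    expect_equal(elastic_modulus(up, m)$E, 3 * E0, tolerance = 1e-9)
    wide <- dplyr::mutate(loop, epsilon = epsilon * 2)
    expect_equal(elastic_modulus(wide, m)$E, E0 / 2, tolerance = 1e-9)
  }
})

test_that("loop-fit is less variable than extrema under contour noise", {
  ests <- purrr::map_dfr(1:200, function(s) {
    spec <- quarter_phase_spec(noise_sd_contour = 0.08, seed = s)
    ph <- generate_phantom(spec)
    st <- strain_series(ph$contours, "min-pressure", ph$pressure)
    loop <- build_ps_loop(st, ph$pressure)
    tibble::tibble(fit = elastic_modulus(loop, "loop-fit")$E,
                   ext = elastic_modulus(loop, "extrema")$E)
  })
  expect_lt(var(ests$fit), var(ests$ext))
})

test_that("modulus ratio compares like timepoints only", {
  loop73 <- tibble::tibble(epsilon = c(0, 0.1, 0.2), p_mmHg = c(0, 7.3, 14.6))
  loop10 <- tibble::tibble(epsilon = c(0, 0.1, 0.2), p_mmHg = c(0, 1, 2))
  e_t <- elastic_modulus(loop73, tissue = "itev", timepoint = 0)
  e_n <- elastic_modulus(loop10, tissue = "native", timepoint = 0)
  expect_equal(modulus_ratio(e_t, e_n), 7.3, tolerance = 1e-9)
  expect_equal(modulus_ratio(e_n, e_n), 1)
  e_late <- elastic_modulus(loop10, tissue = "native", timepoint = 12)
  expect_error(modulus_ratio(e_t, e_late), class = "va_validation_error")
})

test_that("tidy and glance expose the modulus record", {
  loop <- tibble::tibble(epsilon = c(0, 0.1, 0.2), p_mmHg = c(5, 10, 15))
  rec <- elastic_modulus(loop, subject_id = "dog_1", tissue = "itev",
                         timepoint = 2.5)
  td <- tidy(rec)
  expect_equal(td$estimate, 50)
  expect_equal(td$tissue, "itev")
  gl <- glance(rec)
  expect_named(gl, c("E", "method", "n", "strain_range", "pressure_range",
                     "cycle_count"))
  expect_equal(gl$n, 3L)
})
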