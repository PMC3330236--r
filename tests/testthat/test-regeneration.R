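test_that("RS endpoint identities hold exactly", {
  expect_equal(regeneration_score(1, 1, 7.3, 1), 100)       # modulus-matched
  expect_equal(regeneration_score(7.3, 1, 7.3, 1), 0)       # at implantation
  expect_equal(regeneration_score(1.63, 1, 7.3, 1), 90)     # direct formula
})

test_that("RS validates its inputs", {
  expect_error(regeneration_score(1, 1, 5, 5), class = "va_undefined_score")
  expect_error(regeneration_score(-1, 1, 7.3, 1),
               class = "va_validation_error")
  expect_error(regeneration_score(1, 1, Inf, 1),
               class = "va_validation_error")
})

test_that("RS is invariant under common rescaling of all four moduli", {
  withr::with_seed(21, {
    for (i in 1:200) {
      q <- stats::runif(4, 0.1, 20)
      if (q[3] == q[4]) next
      c <- stats::runif(1, 0.01, 50)
      expect_equal(regeneration_score(q[1], q[2], q[3], q[4]),
                   regeneration_score(c * q[1], c * q[2], c * q[3], c * q[4]),
                   tolerance = 1e-9)
    }
  })
})

test_that("RS decreases as the current modulus mismatch grows", {
  gaps <- seq(0, 5, by = 0.25)
  rs <- vapply(gaps, function(g) regeneration_score(1 + g, 1, 7.3, 1),
               numeric(1))
  expect_true(all(diff(rs) < 0))
  # an overshoot beyond the baseline mismatch goes negative, unclamped
  expect_lt(regeneration_score(10, 1, 7.3, 1), 0)
})

test_that("signed RS keeps the direction of the mismatch", {
  expect_equal(regeneration_score(1.63, 1, 7.3, 1, signed = TRUE), 90)
  # under-stiff graft with a stiff baseline: signed goes above 100
  expect_gt(regeneration_score(0.5, 1, 7.3, 1, signed = TRUE), 100)
  expect_lt(regeneration_score(0.5, 1, 7.3, 1), 100)
})

test_that("cohort RS uses each animal's own baseline", {
  coh <- generate_cohort(cohort_spec(between_animal_cv = 0,
                                     measurement_cv = 0, seed = 5))
  rs <- cohort_rs(coh)
  s <- rs_summary(rs)
  # zero noise: no dispersion at any timepoint
  expect_equal(s$sem_rs, rep(0, nrow(s)))
  expect_equal(s$n, rep(7L, nrow(s)))
  expect_equal(s$mean_rs[s$timepoint_months == 0], 0)
  # ratio trajectory {7.3, 2.3, ...} with native mean fixed:
  # RS_t = (1 - |r_t - 1| / 6.3) * 100
  r <- c(2.3, 1.1, 1.0, 1.4, 1.1)
  expect_equal(s$mean_rs[s$timepoint_months > 0],
               (1 - abs(r - 1) / 6.3) * 100, tolerance = 1e-9)
  # a timepoint with ratio exactly 1 scores 100%
  expect_equal(s$mean_rs[s$timepoint_months == 6], 100)
  # 7 animals -> 7 scores per post-baseline timepoint
  expect_equal(sum(rs$timepoint_months == 1), 7L)
})

test_that("a missing month-0 baseline is reported by animal", {
  coh <- generate_cohort(cohort_spec(seed = 6))
  broken <- dplyr::filter(coh, !(animal_id == "animal_03" &
                                   timepoint_months == 0))
  expect_error(cohort_rs(broken), "animal_03", class = "va_missing_baseline")
})

test_that("averaging RS per animal differs from RS of group means", {
  spec_noisy <- cohort_spec(between_animal_cv = 0.2, measurement_cv = 0.1,
                            seed = 9)
  coh <- generate_cohort(spec_noisy)
  s <- rs_summary(cohort_rs(coh))
  means <- coh |>
    dplyr::group_by(timepoint_months, tissue) |>
    dplyr::summarise(m = mean(modulus), .groups = "drop") |>
    tidyr::pivot_wider(names_from = tissue, values_from = m)
  base <- dplyr::filter(means, timepoint_months == 0)
  rs_of_means <- regeneration_score(means$itev, means$native,
                                    base$itev, base$native)
  late <- s$timepoint_months > 0
  expect_false(any(abs(s$mean_rs[late] - rs_of_means[late]) < 1e-6))

  # but the two coincide in the zero-variance case
  coh0 <- generate_cohort(cohort_spec(between_animal_cv = 0,
                                      measurement_cv = 0, seed = 9))
  s0 <- rs_summary(cohort_rs(coh0))
  means0 <- coh0 |>
    dplyr::group_by(timepoint_months, tissue) |>
    dplyr::summarise(m = mean(modulus), .groups = "drop") |>
    tidyr::pivot_wider(names_from = tissue, values_from = m)
  base0 <- dplyr::filter(means0, timepoint_months == 0)
  expect_equal(s0$mean_rs,
               regeneration_score(means0$itev, means0$native,
                                  base0$itev, base0$native),
               tolerance = 1e-9)
})
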