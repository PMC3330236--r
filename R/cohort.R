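#' Specify a synthetic remodeling cohort
#'
#' Parameters of a simulated animal cohort in which each animal carries a
#' graft whose elastic modulus is followed against the native vessel over
#' fixed timepoints.  Moduli are drawn lognormally (moduli are positive,
#' and biological + measurement scatter is multiplicative): each animal gets
#' a lognormal random effect with coefficient of variation
#' `between_animal_cv`, and every measurement an independent lognormal
#' deviate with `measurement_cv`; both draws are mean-preserving.
#'
#' The default trajectory of graft/native stiffness ratios — 7.3 at
#' implantation falling to about 1 by 2.5 months — reproduces the remodeling
#' regime of a caval graft whose stiff scaffold is resorbed while native-like
#' tissue forms, with n = 7 animals followed to 24 months.
#'
#' @param n_animals Number of animals.
#' @param timepoints Follow-up times in months, strictly increasing and
#'   including 0 (implantation).
#' @param modulus_ratio_means Expected graft/native modulus ratio at each
#'   timepoint (same length as `timepoints`).
#' @param native_modulus_mean Expected native modulus (mmHg per unit strain).
#' @param between_animal_cv,measurement_cv Coefficients of variation in
#'   \[0, 1).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_animals = 7,
                        timepoints = c(0, 1, 2.5, 6, 12, 24),
                        modulus_ratio_means = c(7.3, 2.3, 1.1, 1.0, 1.4, 1.1),
                        native_modulus_mean = 30,
                        between_animal_cv = 0.15,
                        measurement_cv = 0.05,
                        seed = 1L) {
  check_scalar(n_animals, "n_animals", lower = 1, integerish = TRUE)
  check_scalar(native_modulus_mean, "native_modulus_mean", lower = 0,
               strict_lower = TRUE)
  check_scalar(between_animal_cv, "between_animal_cv", lower = 0, upper = 1)
  check_scalar(measurement_cv, "measurement_cv", lower = 0, upper = 1)
  if (between_animal_cv >= 1 || measurement_cv >= 1) {
    va_abort("CVs must be in [0, 1).", "va_validation_error")
  }
  check_scalar(seed, "seed", integerish = TRUE)
  if (!is.numeric(timepoints) || length(timepoints) < 1L ||
      is.unsorted(timepoints, strictly = TRUE) || !0 %in% timepoints) {
    va_abort("`timepoints` must be strictly increasing and include 0.",
             "va_validation_error")
  }
  if (!is.numeric(modulus_ratio_means) ||
      length(modulus_ratio_means) != length(timepoints) ||
      any(modulus_ratio_means <= 0)) {
    va_abort(paste("`modulus_ratio_means` must be positive and match",
                   "`timepoints` in length."), "va_validation_error")
  }
  structure(
    list(
      n_animals = as.integer(n_animals),
      timepoints = timepoints,
      modulus_ratio_means = modulus_ratio_means,
      native_modulus_mean = native_modulus_mean,
      between_animal_cv = between_animal_cv,
      measurement_cv = measurement_cv,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# mean-preserving lognormal deviates at a given CV
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic remodeling cohort
#'
#' Draws per-animal, per-timepoint elastic moduli for the native vessel and
#' the graft according to a [cohort_spec()].  Month-0 rows are always
#' present, so per-animal regeneration scores are computable downstream.
#' With both CVs at zero every graft/native ratio equals the specified mean
#' exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per animal x timepoint x tissue:
#'   `animal_id`, `timepoint_months`, `tissue` (`"native"`/`"itev"`),
#'   `modulus`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    va_abort("`spec` must be created by `cohort_spec()`.",
             "va_validation_error")
  }
  withr::with_seed(spec$seed, {
    grid <- tidyr::expand_grid(
      animal = seq_len(spec$n_animals),
      tp = seq_along(spec$timepoints)
    )
    # animal-level multiplicative effects, one per tissue channel
    eff_native <- rlnorm_cv(spec$n_animals, 1, spec$between_animal_cv)
    eff_itev <- rlnorm_cv(spec$n_animals, 1, spec$between_animal_cv)
    n <- nrow(grid)
    native <- spec$native_modulus_mean * eff_native[grid$animal] *
      rlnorm_cv(n, 1, spec$measurement_cv)
    itev <- spec$native_modulus_mean *
      spec$modulus_ratio_means[grid$tp] * eff_itev[grid$animal] *
      rlnorm_cv(n, 1, spec$measurement_cv)
    tibble(
      animal_id = sprintf("animal_%02d", rep(grid$animal, 2L)),
      timepoint_months = spec$timepoints[rep(grid$tp, 2L)],
      tissue = rep(c("native", "itev"), each = n),
      modulus = c(native, itev)
    ) |>
      dplyr::arrange(.data$animal_id, .data$timepoint_months, .data$tissue)
  })
}
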