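#' Regeneration score (RS)
#'
#' Scores how closely a tissue-engineered vessel's elastic modulus has
#' converged to the native vessel's, normalized by how far apart they were
#' immediately after implantation:
#' \deqn{RS = \left(1 - \frac{|E_T - E_N|}{|E_{T0} - E_{N0}|}\right)
#'   \times 100\%}
#' where \eqn{E_T, E_N} are the graft and native moduli at the evaluation
#' time and \eqn{E_{T0}, E_{N0}} the same pair immediately after
#' implantation.  RS = 100% means the graft's modulus matches the native
#' vessel (complete remodeling); RS = 0% means the mismatch is unchanged
#' from implantation (none).  RS may be negative if the mismatch has grown;
#' it is deliberately not clamped.
#'
#' Absolute differences make the score symmetric in over- vs under-stiffness;
#' set `signed = TRUE` to use raw differences instead, in which case the sign
#' of the baseline mismatch orients the score.
#'
#' @param e_t,e_n Graft (iTEV) and native moduli at the evaluation time
#'   (mmHg per unit strain, > 0).  Vectorized.
#' @param e_t0,e_n0 The same pair immediately after implantation; their
#'   difference must be nonzero.
#' @param signed Use signed differences instead of absolute ones.
#' @return RS in percent.
#' @export
#' @examples
#' regeneration_score(1, 1, 7.3, 1)       # 100: modulus-matched
#' regeneration_score(7.3, 1, 7.3, 1)     # 0: unchanged from implantation
#' regeneration_score(1.63, 1, 7.3, 1)    # 90: mismatch shrunk to a tenth
regeneration_score <- function(e_t, e_n, e_t0, e_n0, signed = FALSE) {
  vals <- c(e_t, e_n, e_t0, e_n0)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    va_abort("All four moduli must be finite and positive.",
             "va_validation_error")
  }
  base <- e_t0 - e_n0
  if (any(base == 0)) {
    va_abort("Undefined score: baseline moduli are equal (E_T0 = E_N0).",
             "va_undefined_score")
  }
  if (signed) {
    (1 - (e_t - e_n) / base) * 100
  } else {
    (1 - abs(e_t - e_n) / abs(base)) * 100
  }
}

#' Per-animal regeneration scores for a cohort
#'
#' Computes RS per animal and follow-up timepoint, using each animal's own
#' implantation (month 0) moduli as the baseline — regeneration is judged
#' per implant, not against a group average.
#'
#' @param cohort Long cohort table with columns `animal_id`,
#'   `timepoint_months`, `tissue` (`"native"`/`"itev"`), `modulus`, e.g.
#'   from [generate_cohort()].
#' @param signed Passed to [regeneration_score()].
#' @return A `cohort_rs` tibble with `animal_id`, `timepoint_months`,
#'   `rs_percent` (0 at month 0 by construction).  Summarise with
#'   [rs_summary()].
#' @export
cohort_rs <- function(cohort, signed = FALSE) {
  check_columns(cohort, c("animal_id", "timepoint_months", "tissue",
                          "modulus"), "Cohort table")
  wide <- cohort |>
    dplyr::select("animal_id", "timepoint_months", "tissue", "modulus") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "modulus")
  check_columns(wide, c("native", "itev"), "Cohort table (after widening)")

  baseline <- dplyr::filter(wide, .data$timepoint_months == 0)
  no_base <- setdiff(unique(wide$animal_id), baseline$animal_id)
  if (length(no_base) > 0L) {
    va_abort(sprintf("Missing month-0 baseline for animal(s): %s.",
                     paste(no_base, collapse = ", ")),
             "va_missing_baseline")
  }
  baseline <- dplyr::select(baseline, "animal_id",
                            itev0 = "itev", native0 = "native")

  out <- wide |>
    dplyr::inner_join(baseline, by = "animal_id") |>
    dplyr::mutate(rs_percent = regeneration_score(
      .data$itev, .data$native, .data$itev0, .data$native0,
      signed = signed)) |>
    dplyr::select("animal_id", "timepoint_months", "rs_percent") |>
    dplyr::arrange(.data$animal_id, .data$timepoint_months)
  class(out) <- c("cohort_rs", class(out))
  out
}

#' Per-timepoint RS summary (mean +/- SEM)
#'
#' @param rs A `cohort_rs` table (or any tibble with `timepoint_months`,
#'   `rs_percent`).
#' @return A tibble with `timepoint_months`, `mean_rs`, `sem_rs`, `n`.
#' @export
rs_summary <- function(rs) {
  check_columns(rs, c("timepoint_months", "rs_percent"), "RS table")
  rs |>
    dplyr::group_by(.data$timepoint_months) |>
    dplyr::summarise(
      mean_rs = mean(.data$rs_percent),
      sem_rs = sd(.data$rs_percent) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Plot cohort regeneration scores over time
#'
#' Mean +/- SEM trajectory of RS across follow-up timepoints, the standard
#' summary figure for a remodeling cohort.
#'
#' @param object A `cohort_rs` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_rs <- function(object, ...) {
  s <- rs_summary(object) |>
    dplyr::filter(.data$timepoint_months > 0)
  ggplot2::ggplot(s, ggplot2::aes(.data$timepoint_months, .data$mean_rs)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rs - .data$sem_rs,
      ymax = .data$mean_rs + .data$sem_rs), width = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "months after implantation",
                  y = "regeneration score (%)") +
    ggplot2::theme_minimal()
}
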