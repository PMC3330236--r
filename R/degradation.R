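#' Published scaffold degradation series
#'
#' The in-vitro degradation measurements of the biodegradable vascular
#' scaffold (PGA knitted fibers + P(LA/CL) sponge with P(GA/CL) monofilament
#' reinforcement) soaked in PBS at 37 degrees C: tensile strength per cm
#' width (N) at weeks 0-9 and weight-average molecular weight (Da) at weeks
#' 0-25, exactly as published.  The strength series loses half its starting
#' value between weeks 2 and 3 and is nearly gone by week 9; the molecular
#' weight shows gradual hydrolysis with a late plateau.
#'
#' @return A list of two decay-series tibbles, `strength` and `mw`, each
#'   with columns `time_weeks`, `value`, `quantity`
#'   (`"strength_N"` / `"mw_da"`).
#' @export
#' @examples
#' deg <- load_printed_degradation()
#' deg$strength$value[1] # 9.3 N at week 0
load_printed_degradation <- function() {
  path <- system.file("extdata", "scaffold_degradation.csv",
                      package = "vesselastica", mustWork = TRUE)
  all <- readr::read_csv(path, show_col_types = FALSE)
  list(
    strength = dplyr::filter(all, .data$quantity == "strength_N"),
    mw = dplyr::filter(all, .data$quantity == "mw_da")
  )
}

validate_decay_series <- function(series) {
  check_columns(series, c("time_weeks", "value"), "Decay series")
  if (nrow(series) < 3L) {
    va_abort("A decay series needs at least 3 points.", "va_validation_error")
  }
  if (is.unsorted(series$time_weeks, strictly = TRUE)) {
    va_abort("Decay-series times must be strictly increasing.",
             "va_validation_error")
  }
  if (any(!is.finite(series$value)) || any(series$value <= 0)) {
    va_abort("Decay-series values must be positive.", "va_validation_error")
  }
  invisible(series)
}

#' Fit first-order decay kinetics
#'
#' Hydrolytic scaffold degradation is modeled as first-order kinetics,
#' \eqn{v(t) = v_0 e^{-kt}}, fit by least squares on the log scale
#' (a straight line on \eqn{(t, \ln v)}).  The log-space RMSE is reported so
#' departures from single-exponential behaviour — e.g. a late molecular-
#' weight plateau — are visible rather than silently absorbed.
#'
#' @param series Decay series tibble (`time_weeks`, `value` > 0).
#' @return A `decay_fit` object with `v0` (fitted value at t = 0), `k`
#'   (per-week rate), `half_life` (= ln 2 / k; `NA` when the series does not
#'   decay), `rmse` (log space), and the underlying `lm` fit.  Use
#'   [tidy()] / [glance()] / [autoplot()].
#' @export
#' @examples
#' s <- tibble::tibble(time_weeks = 0:4, value = 10 * exp(-0.5 * (0:4)))
#' fit_exponential(s)$k # 0.5
fit_exponential <- function(series) {
  validate_decay_series(series)
  fit <- lm(log(value) ~ time_weeks, data = series)
  k <- -unname(coef(fit)[2L])
  if (abs(k) < 1e-12) k <- 0  # constant series: numerically zero slope
  v0 <- exp(unname(coef(fit)[1L]))
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  structure(
    list(
      model = "exponential",
      v0 = v0,
      k = k,
      half_life = if (k > 0) log(2) / k else NA_real_,
      rmse = rmse,
      n = nrow(series),
      quantity = series[["quantity"]][1L] %||% NA_character_,
      series = series,
      fit = fit
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit (%d points): v0 = %.4g, k = %.4g /week\n",
    x$n, x$v0, x$k))
  cat(sprintf("  half-life = %s weeks, log-space RMSE = %.3g\n",
              if (is.na(x$half_life)) "undefined" else
                sprintf("%.3g", x$half_life), x$rmse))
  invisible(x)
}

#' @rdname fit_exponential
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("log_v0", "k"),
    estimate = c(unname(coef(x$fit)[1L]), x$k),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]) * c(1, -1),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_exponential
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(v0 = x$v0, k = x$k, half_life = x$half_life, rmse = x$rmse,
         n = x$n, r.squared = summary(x$fit)$r.squared)
}

#' Plot a decay fit
#'
#' Data and fitted exponential on a log value axis, where first-order decay
#' is a straight line and departures from it (late plateaus) are obvious.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, ...) {
  s <- object$series
  grid <- tibble(time_weeks = seq(min(s$time_weeks), max(s$time_weeks),
                                  length.out = 200))
  grid$value <- object$v0 * exp(-object$k * grid$time_weeks)
  ggplot2::ggplot(s, ggplot2::aes(.data$time_weeks, .data$value)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "weeks", y = "value (log scale)",
                  title = sprintf("first-order decay: k = %.3g /week", object$k)) +
    ggplot2::theme_minimal()
}

#' Time to reach a fraction of the initial value
#'
#' When does a decaying quantity first reach `fraction` of its week-0 value?
#' Two methods:
#' * `"interpolate"` (default): linear interpolation in value between the
#'   two measured points that bracket the threshold — the direct read-off
#'   from the measurement table;
#' * `"fit"`: \eqn{\ln(1/f) / k} from the first-order fit.
#'
#' @param series Decay series tibble.
#' @param fraction Target fraction of the initial value, in (0, 1].
#' @param method `"interpolate"` or `"fit"`.
#' @return Time in weeks.
#' @export
#' @examples
#' deg <- load_printed_degradation()
#' time_to_fraction(deg$strength, 0.5) # ~2.2 weeks: half strength
time_to_fraction <- function(series, fraction,
                             method = c("interpolate", "fit")) {
  validate_decay_series(series)
  method <- match.arg(method)
  check_scalar(fraction, "fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (method == "fit") {
    k <- fit_exponential(series)$k
    if (k <= 0) {
      va_abort("Threshold never crossed: fitted rate is not positive.",
               "va_not_crossed")
    }
    return(log(1 / fraction) / k)
  }
  target <- fraction * series$value[1L]
  below <- which(series$value <= target)
  if (length(below) == 0L) {
    va_abort(sprintf(
      "Threshold never crossed: series never reaches %.3g of its initial value.",
      fraction), "va_not_crossed")
  }
  j <- below[1L]
  if (j == 1L) return(series$time_weeks[1L])
  t1 <- series$time_weeks[j - 1L]; v1 <- series$value[j - 1L]
  t2 <- series$time_weeks[j];      v2 <- series$value[j]
  t1 + (v1 - target) / (v1 - v2) * (t2 - t1)
}

#' First measured time at or below an absolute threshold
#'
#' The earliest measured timepoint whose value is `<= threshold` — the
#' conservative table read-off for statements like "strength was entirely
#' lost within N weeks".
#'
#' @param series Decay series tibble.
#' @param threshold Absolute threshold in the series' units.
#' @return Time in weeks.
#' @export
#' @examples
#' deg <- load_printed_degradation()
#' first_time_below(deg$strength, 0.1) # week 9
first_time_below <- function(series, threshold) {
  validate_decay_series(series)
  check_scalar(threshold, "threshold")
  j <- which(series$value <= threshold)
  if (length(j) == 0L) {
    va_abort(sprintf("Threshold never crossed: no value is <= %.3g.",
                     threshold), "va_not_crossed")
  }
  series$time_weeks[j[1L]]
}
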