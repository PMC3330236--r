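#' Variance-screened two-group comparison
#'
#' The two-group protocol used throughout this kind of study: groups are
#' first screened for equality of variances at `var_alpha`; if the screen
#' does not reject, an unpaired Student's t-test (equal variances) is used,
#' otherwise the Mann-Whitney U test.  The screen outcome is recorded in the
#' result so every test choice is auditable.
#'
#' The original protocol does not pin down which variance test backs the
#' screen, so it is configurable: `"f"` (F test, default), `"levene"`
#' (Brown-Forsythe, via the car package), or `"bartlett"`.  A screen that
#' cannot be computed (e.g. both groups constant) falls back to the
#' nonparametric route.
#'
#' @param data A data frame in long format.
#' @param value,group Columns (tidy-eval) holding the measurement and the
#'   group label; exactly two groups, each with n >= 3.
#' @param var_test Variance screen to use.
#' @param var_alpha Significance level of the screen.
#' @param alpha Significance level of the comparison itself.
#' @return A `vessel_comparison` object; see [tidy.vessel_comparison()].
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 5),
#'                     y = c(1:5, 6:10))
#' compare_two(d, y, g)$test
compare_two <- function(data, value, group,
                        var_test = c("f", "levene", "bartlett"),
                        var_alpha = 0.05, alpha = 0.05) {
  var_test <- match.arg(var_test)
  prep <- prep_groups(data, {{ value }}, {{ group }})
  if (dplyr::n_distinct(prep$group) != 2L) {
    va_abort("`compare_two()` needs exactly 2 groups.", "va_validation_error")
  }
  if (any(table(prep$group) < 3L)) {
    va_abort("Each group needs n >= 3.", "va_validation_error")
  }

  screen <- variance_screen(prep, var_test, var_alpha)
  if (screen$equal) {
    ht <- stats::t.test(value ~ group, data = prep, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- stats::wilcox.test(value ~ group, data = prep, exact = FALSE)
    test <- "mann-whitney"
  }
  new_comparison(test, ht, screen, prep, alpha,
                 comparisons = NULL, baseline = NULL)
}

#' Variance-screened many-group comparison against a baseline
#'
#' The many-group protocol: a variance screen (Bartlett by default, Levene
#' optional, or `"none"` to force the parametric route) decides between
#' one-way ANOVA followed by Dunnett's many-to-one post-hoc comparisons
#' against the named baseline group — critical values from the single-step
#' multivariate-t formulation — and the Kruskal-Wallis test.  Only
#' baseline-vs-other contrasts are tested on the Dunnett route; no
#' pairwise comparisons among the non-baseline groups are made.
#'
#' @inheritParams compare_two
#' @param baseline Baseline (control) group label for the many-to-one
#'   comparisons; required on the Dunnett route.
#' @param var_test `"bartlett"`, `"levene"`, or `"none"`.
#' @return A `vessel_comparison`; on the Dunnett route its `comparisons`
#'   tibble has one row per baseline-vs-group contrast.
#' @export
compare_many <- function(data, value, group, baseline = NULL,
                         var_test = c("bartlett", "levene", "none"),
                         var_alpha = 0.05, alpha = 0.05) {
  var_test <- match.arg(var_test)
  prep <- prep_groups(data, {{ value }}, {{ group }})
  k <- dplyr::n_distinct(prep$group)
  if (k < 3L) {
    va_abort("`compare_many()` needs at least 3 groups.",
             "va_validation_error")
  }

  screen <- if (var_test == "none") {
    list(method = "none", statistic = NA_real_, p = NA_real_, equal = TRUE)
  } else {
    variance_screen(prep, var_test, var_alpha)
  }

  if (screen$equal) {
    if (is.null(baseline)) {
      va_abort("A `baseline` group is required for Dunnett comparisons.",
               "va_validation_error")
    }
    baseline <- as.character(baseline)
    if (!baseline %in% prep$group) {
      va_abort(sprintf("Baseline group '%s' not found in the data.",
                       baseline), "va_validation_error")
    }
    prep$group <- stats::relevel(factor(prep$group), ref = baseline)
    fit <- aov(value ~ group, data = prep)
    omnibus <- summary(fit)[[1L]]
    dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett")))
    comparisons <- tibble(
      comparison = names(dn$test$coefficients),
      estimate = unname(dn$test$coefficients),
      statistic = unname(dn$test$tstat),
      p_adj = unname(dn$test$pvalues),
      significant = unname(dn$test$pvalues) < alpha
    )
    ht <- list(statistic = omnibus[["F value"]][1L],
               p.value = omnibus[["Pr(>F)"]][1L],
               method = "One-way ANOVA + Dunnett")
    test <- "anova+dunnett"
  } else {
    ht <- stats::kruskal.test(value ~ group, data = prep)
    comparisons <- NULL
    test <- "kruskal-wallis"
  }
  new_comparison(test, ht, screen, prep, alpha, comparisons, baseline)
}

prep_groups <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  if (!is.numeric(v) || any(!is.finite(v))) {
    va_abort("The value column must be finite numeric.",
             "va_validation_error")
  }
  data.frame(value = v, group = as.character(g))
}

variance_screen <- function(prep, var_test, var_alpha) {
  res <- tryCatch(
    switch(var_test,
      "f" = {
        ht <- stats::var.test(value ~ group, data = prep)
        list(statistic = unname(ht$statistic), p = ht$p.value)
      },
      "levene" = {
        if (!requireNamespace("car", quietly = TRUE)) {
          va_abort("The car package is required for the Levene screen.",
                   "va_validation_error")
        }
        ht <- car::leveneTest(value ~ factor(group), data = prep)
        list(statistic = ht[1L, "F value"], p = ht[1L, "Pr(>F)"])
      },
      "bartlett" = {
        ht <- stats::bartlett.test(value ~ group, data = prep)
        list(statistic = unname(ht$statistic), p = ht$p.value)
      }
    ),
    error = function(e) list(statistic = NA_real_, p = NA_real_)
  )
  equal <- is.finite(res$p) && res$p >= var_alpha
  list(method = var_test, statistic = res$statistic, p = res$p,
       equal = equal)
}

new_comparison <- function(test, ht, screen, prep, alpha, comparisons,
                           baseline) {
  summary_tbl <- prep |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- unname(ht$p.value)
  structure(
    list(
      test = test,
      statistic = unname(ht$statistic),
      p_value = p,
      significant = is.finite(p) && p < alpha,
      alpha = alpha,
      variance_screen = screen,
      summary = summary_tbl,
      comparisons = comparisons,
      baseline = baseline
    ),
    class = "vessel_comparison"
  )
}

#' @export
print.vessel_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (variance screen: %s, p = %s -> %s)\n",
              x$test, x$variance_screen$method,
              format(signif(x$variance_screen$p, 3)),
              if (x$variance_screen$equal) "equal" else "unequal"))
  cat(sprintf("  statistic = %.4g, p = %.4g, %s at alpha = %g\n",
              x$statistic, x$p_value,
              if (x$significant) "significant" else "NS", x$alpha))
  print(x$summary)
  if (!is.null(x$comparisons)) {
    cat(sprintf("Dunnett many-to-one vs baseline '%s':\n", x$baseline))
    print(x$comparisons)
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' `tidy()` returns the per-contrast table (Dunnett route) or the single
#' omnibus row; `glance()` returns the one-row summary of the whole
#' procedure, including the variance-screen outcome that selected the test.
#'
#' @param x A `vessel_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vessel_comparison <- function(x, ...) {
  if (!is.null(x$comparisons)) return(x$comparisons)
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         significant = x$significant)
}

#' @rdname tidy.vessel_comparison
#' @export
glance.vessel_comparison <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = x$statistic,
    p_value = x$p_value,
    significant = x$significant,
    alpha = x$alpha,
    screen_method = x$variance_screen$method,
    screen_p = x$variance_screen$p,
    variances_equal = x$variance_screen$equal,
    n_groups = nrow(x$summary)
  )
}
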