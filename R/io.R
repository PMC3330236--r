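#' Read and write the pipeline's CSV dialects
#'
#' Every stage of the pipeline exchanges plain CSV so intermediates stay
#' independently inspectable.  The dialects are:
#' * contour series: `frame_index`, `t_seconds`, `vertex_index`, `x_mm`,
#'   `y_mm`
#' * pressure trace: `t_seconds`, `p_mmHg`
#' * strain series: `frame_index`, `t_seconds`, `L_mm`, `epsilon`
#' * cohort table: `animal_id`, `timepoint_months`, `tissue`, `modulus`
#' * decay series: `time_weeks`, `value`, `quantity`
#'
#' The readers validate the expected columns and error on mismatch.
#'
#' @param x The tibble to write.
#' @param path File path.
#' @return Readers return a validated tibble; writers return `path`
#'   invisibly.
#' @name csv_dialects
NULL

write_dialect <- function(x, path, cols) {
  check_columns(x, cols, basename(path))
  readr::write_csv(dplyr::select(x, dplyr::all_of(cols)), path)
  invisible(path)
}

read_dialect <- function(path, cols) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, cols, basename(path))
  x
}

.dialects <- list(
  contours = c("frame_index", "t_seconds", "vertex_index", "x_mm", "y_mm"),
  pressure = c("t_seconds", "p_mmHg"),
  strain = c("frame_index", "t_seconds", "L_mm", "epsilon"),
  cohort = c("animal_id", "timepoint_months", "tissue", "modulus"),
  decay = c("time_weeks", "value", "quantity")
)

#' @rdname csv_dialects
#' @export
write_contours_csv <- function(x, path) write_dialect(x, path, .dialects$contours)
#' @rdname csv_dialects
#' @export
read_contours_csv <- function(path) read_dialect(path, .dialects$contours)
#' @rdname csv_dialects
#' @export
write_pressure_csv <- function(x, path) write_dialect(x, path, .dialects$pressure)
#' @rdname csv_dialects
#' @export
read_pressure_csv <- function(path) read_dialect(path, .dialects$pressure)
#' @rdname csv_dialects
#' @export
write_strain_csv <- function(x, path) write_dialect(x, path, .dialects$strain)
#' @rdname csv_dialects
#' @export
read_strain_csv <- function(path) read_dialect(path, .dialects$strain)
#' @rdname csv_dialects
#' @export
write_cohort_csv <- function(x, path) write_dialect(x, path, .dialects$cohort)
#' @rdname csv_dialects
#' @export
read_cohort_csv <- function(path) read_dialect(path, .dialects$cohort)
#' @rdname csv_dialects
#' @export
write_decay_csv <- function(x, path) write_dialect(x, path, .dialects$decay)
#' @rdname csv_dialects
#' @export
read_decay_csv <- function(path) read_dialect(path, .dialects$decay)
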