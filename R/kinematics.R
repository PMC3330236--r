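#' Circumferential length of a closed lumen contour
#'
#' Perimeter of the closed polygon through the contour vertices: the sum of
#' Euclidean edge lengths including the closing edge back to the first vertex.
#' This is the time-dependent luminal circumferential length L that the strain
#' definition is built on.
#'
#' The perimeter is computed on the polygon exactly as given.  Vertex density
#' does not bias a polygon perimeter (collinear subdivision is length
#' preserving), so no resampling is applied here; see [resample_contour()]
#' for the uniform arc-length helper used where vertex placement is
#' acquisition-determined.
#'
#' @param contour A data frame with `x_mm`, `y_mm` columns, or a two-column
#'   numeric matrix, listing the vertices of one closed contour in order (the
#'   first vertex is not repeated at the end).
#' @return The perimeter in the units of the coordinates (mm).
#' @export
#' @examples
#' square <- tibble::tibble(x_mm = c(0, 1, 1, 0), y_mm = c(0, 0, 1, 1))
#' circumferential_length(square) # 4
circumferential_length <- function(contour) {
  xy <- as_contour_matrix(contour)
  if (nrow(xy) < 3L) {
    va_abort("A closed contour needs at least 3 vertices.",
             "va_validation_error")
  }
  nxt <- c(seq_len(nrow(xy))[-1L], 1L)
  sum(sqrt(rowSums((xy[nxt, , drop = FALSE] - xy)^2)))
}

as_contour_matrix <- function(contour) {
  if (is.data.frame(contour)) {
    check_columns(contour, c("x_mm", "y_mm"), "Contour")
    xy <- cbind(contour$x_mm, contour$y_mm)
  } else if (is.matrix(contour) && ncol(contour) == 2L) {
    xy <- contour
  } else {
    va_abort("`contour` must be a data frame with x_mm/y_mm or an n x 2 matrix.",
             "va_validation_error")
  }
  if (!all(is.finite(xy))) {
    va_abort("Contour coordinates must be finite.", "va_validation_error")
  }
  xy
}

# signed (shoelace) area; sign carries orientation
contour_area <- function(contour) {
  xy <- as_contour_matrix(contour)
  nxt <- c(seq_len(nrow(xy))[-1L], 1L)
  sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]) / 2
}

#' Resample a closed contour to uniform arc-length spacing
#'
#' Places `n_out` vertices at equal arc-length intervals along the closed
#' polygon by linear interpolation, so downstream shape statistics do not
#' depend on how densely an acquisition happened to place vertices.
#' Interpolated vertices lie on the original polygon.
#'
#' @param contour Vertices as in [circumferential_length()].
#' @param n_out Number of output vertices (default: same as input).
#' @return A tibble with `x_mm`, `y_mm`.
#' @export
resample_contour <- function(contour, n_out = NULL) {
  xy <- as_contour_matrix(contour)
  n <- nrow(xy)
  if (n < 3L) {
    va_abort("A closed contour needs at least 3 vertices.",
             "va_validation_error")
  }
  n_out <- n_out %||% n
  closed <- rbind(xy, xy[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) {
    va_abort("Contour has zero perimeter.", "va_validation_error")
  }
  target <- total * (seq_len(n_out) - 1L) / n_out
  tibble(
    x_mm = approx(s, closed[, 1], xout = target, ties = "ordered")$y,
    y_mm = approx(s, closed[, 2], xout = target, ties = "ordered")$y
  )
}

#' Fourier-smooth a closed contour
#'
#' Projects the contour's radius-vs-polar-angle profile (about its centroid)
#' onto the first `harmonics` Fourier harmonics by least squares and
#' reconstructs the vertices at their original angles.  Uncorrelated
#' per-vertex tracing noise lives almost entirely in the high harmonics, so
#' this is the standard denoising step before measuring lengths on traced
#' lumen boundaries; shapes that are already band-limited (circles,
#' ellipses) are reproduced exactly.
#'
#' `harmonics` is capped at `(n_vertices - 1) / 2` so the fit stays
#' overdetermined.
#'
#' @param contour Vertices as in [circumferential_length()].
#' @param harmonics Highest harmonic kept (0 keeps only the mean radius).
#' @return A tibble with `x_mm`, `y_mm` at the original polar angles.
#' @export
smooth_contour <- function(contour, harmonics = 8L) {
  xy <- as_contour_matrix(contour)
  n <- nrow(xy)
  if (n < 3L) {
    va_abort("A closed contour needs at least 3 vertices.",
             "va_validation_error")
  }
  check_scalar(harmonics, "harmonics", lower = 0, integerish = TRUE)
  harmonics <- min(as.integer(harmonics), (n - 1L) %/% 2L)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  th <- atan2(xy[, 2] - cy, xy[, 1] - cx)
  r <- sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)
  basis <- matrix(1, n, 1L + 2L * harmonics)
  if (harmonics > 0L) {
    for (k in seq_len(harmonics)) {
      basis[, 2L * k] <- cos(k * th)
      basis[, 2L * k + 1L] <- sin(k * th)
    }
  }
  r_hat <- as.vector(basis %*% stats::lsfit(basis, r, intercept = FALSE)$coefficients)
  tibble(x_mm = cx + r_hat * cos(th), y_mm = cy + r_hat * sin(th))
}

validate_contour_series <- function(contours) {
  check_columns(contours, c("frame_index", "t_seconds", "vertex_index",
                            "x_mm", "y_mm"), "Contour series")
  frames <- dplyr::distinct(contours, .data$frame_index, .data$t_seconds)
  if (nrow(frames) < 2L) {
    va_abort("A contour series needs at least 2 frames.",
             "va_validation_error")
  }
  if (is.unsorted(frames$t_seconds, strictly = TRUE)) {
    va_abort("Frame timestamps must be strictly increasing.",
             "va_validation_error")
  }
  counts <- dplyr::count(contours, .data$frame_index)
  if (any(counts$n < 8L)) {
    va_abort("Each contour needs at least 8 vertices.", "va_validation_error")
  }
  areas <- contours |>
    dplyr::group_by(.data$frame_index) |>
    dplyr::summarise(area = abs(contour_area(
      cbind(.data$x_mm, .data$y_mm))), .groups = "drop")
  if (any(areas$area <= 0)) {
    va_abort("Each contour must enclose positive area.", "va_validation_error")
  }
  invisible(contours)
}

#' Circumferential strain series from a lumen contour series
#'
#' Computes the per-frame circumferential length L(i) and the engineering
#' strain relative to a reference frame,
#' \deqn{\varepsilon_i = (L_i - L_{ref}) / L_{ref},}
#' the standard dimensionless measure of wall distension used to build the
#' pressure-strain loop.
#'
#' @param contours Long-format contour series: `frame_index`, `t_seconds`,
#'   `vertex_index`, `x_mm`, `y_mm` (as produced by [generate_phantom()] or
#'   [segment_lumen()]).
#' @param reference Reference frame selector: `"min-pressure"` (default when
#'   `pressure` is supplied) takes the frame at which the interpolated
#'   pressure is lowest, i.e. the diastolic frame; `"first"` takes frame 1.
#' @param pressure Optional pressure trace (`t_seconds`, `p_mmHg`), required
#'   for the `"min-pressure"` reference.
#' @param smooth_harmonics Contours are denoised with [smooth_contour()]
#'   before their perimeter is measured; set to `NULL` (or 0 is capped
#'   anyway) to keep the raw polygons.  Band-limited shapes are unaffected,
#'   so the default only removes per-vertex tracing noise.
#' @return A tibble with `frame_index`, `t_seconds`, `L_mm`, `epsilon`, and a
#'   `reference_frame` attribute.  `epsilon` is 0 at the reference frame.
#' @export
strain_series <- function(contours,
                          reference = c("min-pressure", "first"),
                          pressure = NULL,
                          smooth_harmonics = 8L) {
  validate_contour_series(contours)
  reference <- match.arg(reference)
  if (reference == "min-pressure" && is.null(pressure)) {
    reference <- "first"
  }
  measure <- if (is.null(smooth_harmonics)) {
    circumferential_length
  } else {
    function(xy) circumferential_length(smooth_contour(xy, smooth_harmonics))
  }

  lengths <- contours |>
    dplyr::group_by(.data$frame_index, .data$t_seconds) |>
    dplyr::summarise(L_mm = measure(
      cbind(.data$x_mm, .data$y_mm)), .groups = "drop") |>
    dplyr::arrange(.data$t_seconds)

  ref_row <- if (reference == "first") {
    1L
  } else {
    check_columns(pressure, c("t_seconds", "p_mmHg"), "Pressure trace")
    p_at_frames <- approx(pressure$t_seconds, pressure$p_mmHg,
                          xout = lengths$t_seconds, rule = 2,
                          ties = "ordered")$y
    which.min(p_at_frames)
  }
  L_ref <- lengths$L_mm[ref_row]
  if (!is.finite(L_ref) || L_ref <= 0) {
    va_abort("Reference circumferential length must be positive.",
             "va_validation_error")
  }

  out <- dplyr::mutate(lengths, epsilon = (.data$L_mm - L_ref) / L_ref)
  attr(out, "reference_frame") <- lengths$frame_index[ref_row]
  out
}
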