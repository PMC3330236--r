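#' Rasterize lumen contours into B-mode-like frames
#'
#' Renders each contour of a series as a grayscale frame with a dark lumen
#' interior, a bright wall band, and a mid-gray exterior, optionally corrupted
#' by multiplicative speckle noise — the minimal appearance model needed to
#' exercise the ray-based lumen segmenter.  Edges are anti-aliased over one
#' pixel so the true boundary is recoverable at subpixel precision.
#'
#' Contours are assumed star-shaped about their centroid (true of the
#' circular phantom family this renderer serves): the boundary radius seen by
#' each pixel is interpolated over vertex polar angle.
#'
#' @param contours Contour series tibble (`frame_index`, `t_seconds`,
#'   `vertex_index`, `x_mm`, `y_mm`).
#' @param image_size Side length of the square frames, pixels.
#' @param speckle_sd SD of log-normal multiplicative speckle (0 = noiseless).
#' @param wall_thickness_mm Thickness of the bright wall band (mm).
#' @param mm_per_px Pixel pitch (mm).  By default chosen so every contour
#'   plus its wall band fits with a 20% margin; if supplied and the contours
#'   do not fit, an error is raised.
#' @param seed Integer seed for the speckle; the global RNG is untouched.
#' @return A `frame_stack`: list with `frames` (list of `image_size` x
#'   `image_size` matrices in \[0, 1\], row = y from the top, column = x) and
#'   `manifest`, a tibble with one row per frame: `frame_index`, `t_seconds`,
#'   `mm_per_px`, `center_x_mm`, `center_y_mm` — the lossless pixel->mm
#'   mapping linking each frame to its source contour:
#'   `x_mm = center_x + (col - (size+1)/2) * mm_per_px`,
#'   `y_mm = center_y - (row - (size+1)/2) * mm_per_px` (y up).
#' @export
rasterize_frames <- function(contours, image_size = 128, speckle_sd = 0,
                             wall_thickness_mm = 1, mm_per_px = NULL,
                             seed = 1L) {
  validate_contour_series(contours)
  check_scalar(image_size, "image_size", lower = 16, integerish = TRUE)
  check_scalar(speckle_sd, "speckle_sd", lower = 0)
  check_scalar(wall_thickness_mm, "wall_thickness_mm", lower = 0,
               strict_lower = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  image_size <- as.integer(image_size)

  cx <- mean(range(contours$x_mm))
  cy <- mean(range(contours$y_mm))
  max_extent <- max(abs(c(contours$x_mm - cx, contours$y_mm - cy)))
  if (is.null(mm_per_px)) {
    # field of view: contour + wall band + 20% margin must fit
    mm_per_px <- 2 * (max_extent + wall_thickness_mm) * 1.2 / image_size
  } else {
    check_scalar(mm_per_px, "mm_per_px", lower = 0, strict_lower = TRUE)
  }
  if (max_extent + wall_thickness_mm >= image_size / 2 * mm_per_px) {
    va_abort("Contours (plus wall band) exceed the image bounds.",
             "va_validation_error")
  }

  ctr <- (image_size + 1) / 2
  px <- seq_len(image_size)
  x_mm <- cx + (px - ctr) * mm_per_px          # by column
  y_mm <- cy - (px - ctr) * mm_per_px          # by row (y up)
  dist_mm <- sqrt(outer(y_mm - cy, x_mm - cx, function(a, b) a^2 + b^2))
  ang <- atan2(outer(y_mm - cy, rep(1, image_size)),
               outer(rep(1, image_size), x_mm - cx))

  lumen_level <- 0.15
  wall_level <- 0.9
  outside_level <- 0.45
  edge_w <- mm_per_px  # one-pixel linear transition

  frames_split <- split(contours, contours$frame_index)
  withr::with_seed(as.integer(seed), {
    frames <- lapply(frames_split, function(fr) {
      # boundary radius about the shared center, as a function of polar angle
      a <- atan2(fr$y_mm - cy, fr$x_mm - cx)
      r <- sqrt((fr$x_mm - cx)^2 + (fr$y_mm - cy)^2)
      o <- order(a)
      a <- a[o]; r <- r[o]
      a_ext <- c(a[length(a)] - 2 * pi, a, a[1L] + 2 * pi)
      r_ext <- c(r[length(r)], r, r[1L])
      rb <- matrix(approx(a_ext, r_ext, xout = as.vector(ang),
                          ties = "ordered")$y, nrow = image_size)
      # radial profile: lumen -> wall (bright) -> outside, soft edges
      ramp_in <- pmin(pmax((dist_mm - rb) / edge_w + 0.5, 0), 1)
      ramp_out <- pmin(pmax(
        (dist_mm - (rb + wall_thickness_mm)) / edge_w + 0.5, 0), 1)
      img <- lumen_level + (wall_level - lumen_level) * ramp_in +
        (outside_level - wall_level) * ramp_out
      if (speckle_sd > 0) {
        img <- img * exp(matrix(stats::rnorm(length(img), 0, speckle_sd),
                                nrow = image_size))
      }
      pmin(pmax(img, 0), 1)
    })
  })

  manifest <- contours |>
    dplyr::distinct(.data$frame_index, .data$t_seconds) |>
    dplyr::mutate(mm_per_px = mm_per_px, center_x_mm = cx, center_y_mm = cy)

  structure(list(frames = unname(frames), manifest = manifest),
            class = "frame_stack")
}

#' Segment the lumen boundary from B-mode-like frames
#'
#' Recovers a closed lumen contour from each frame by casting `n_rays` rays
#' outward from the intensity-weighted lumen centroid (the lumen is the dark
#' pool) and placing the boundary at the maximum outward intensity gradient
#' along each ray, refined to subpixel by parabolic interpolation around the
#' gradient peak.
#'
#' A ray fails when its strongest gradient is below 10% of the frame's
#' intensity range; isolated failures (< 10% of rays) are filled by
#' interpolation over neighbouring rays, more than that raises a
#' segmentation-failure error naming the frame.
#'
#' @param frames A `frame_stack` from [rasterize_frames()].
#' @param n_rays Number of rays (= vertices of the recovered contour).
#' @return A contour series tibble (`frame_index`, `t_seconds`,
#'   `vertex_index`, `x_mm`, `y_mm`) in the mm coordinates of the manifest.
#' @export
segment_lumen <- function(frames, n_rays = 64) {
  if (!inherits(frames, "frame_stack") || length(frames$frames) == 0L) {
    va_abort("`frames` must be a non-empty frame_stack.",
             "va_validation_error")
  }
  check_scalar(n_rays, "n_rays", lower = 8, integerish = TRUE)
  n_rays <- as.integer(n_rays)
  theta <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays

  purrr::map2_dfr(frames$frames, seq_along(frames$frames), function(img, i) {
    man <- frames$manifest[i, ]
    size <- nrow(img)
    rng <- diff(range(img))
    ctr <- (size + 1) / 2

    # intensity-weighted centroid of the dark lumen pool
    thr <- min(img) + 0.4 * max(rng, .Machine$double.eps)
    w <- pmax(thr - img, 0)
    if (sum(w) <= 0 || rng < 1e-6) {
      va_abort(sprintf("Segmentation failed on frame %d: no lumen found.",
                       man$frame_index),
               "va_segmentation_failure")
    }
    col_ix <- matrix(rep(seq_len(size), each = size), nrow = size)
    row_ix <- matrix(rep(seq_len(size), times = size), nrow = size)
    c_col <- sum(w * col_ix) / sum(w)
    c_row <- sum(w * row_ix) / sum(w)

    step <- 0.25
    t_max <- min(c_col - 1, size - c_col, c_row - 1, size - c_row)
    t_seq <- seq(1, t_max, by = step)

    radii_px <- vapply(theta, function(th) {
      # image rows increase downward; +th in mm space is -th in row space
      cols <- c_col + t_seq * cos(th)
      rows <- c_row - t_seq * sin(th)
      prof <- bilinear_sample(img, rows, cols)
      g <- diff(prof) / step
      k <- which.max(g)
      if (!is.finite(g[k]) || g[k] < 0.1 * rng) return(NA_real_)
      # parabolic subpixel refinement on the gradient peak
      t_pk <- t_seq[k] + step / 2
      if (k > 1L && k < length(g)) {
        denom <- g[k - 1L] - 2 * g[k] + g[k + 1L]
        if (is.finite(denom) && denom < 0) {
          off <- 0.5 * (g[k - 1L] - g[k + 1L]) / denom
          t_pk <- t_pk + max(min(off, 0.5), -0.5) * step
        }
      }
      t_pk
    }, numeric(1))

    bad <- !is.finite(radii_px)
    if (mean(bad) >= 0.10) {
      va_abort(sprintf(
        "Segmentation failed on frame %d: %d of %d rays found no boundary.",
        man$frame_index, sum(bad), n_rays), "va_segmentation_failure")
    }
    if (any(bad)) {
      ok <- which(!bad)
      radii_px[bad] <- approx(
        c(theta[ok] - 2 * pi, theta[ok], theta[ok] + 2 * pi),
        rep(radii_px[ok], 3), xout = theta[bad], ties = "ordered")$y
    }

    x_px <- c_col + radii_px * cos(theta)
    y_px <- c_row - radii_px * sin(theta)
    tibble(
      frame_index = man$frame_index,
      t_seconds = man$t_seconds,
      vertex_index = seq_len(n_rays),
      x_mm = man$center_x_mm + (x_px - ctr) * man$mm_per_px,
      y_mm = man$center_y_mm - (y_px - ctr) * man$mm_per_px
    )
  })
}

bilinear_sample <- function(img, rows, cols) {
  r0 <- pmin(pmax(floor(rows), 1L), nrow(img) - 1L)
  c0 <- pmin(pmax(floor(cols), 1L), ncol(img) - 1L)
  fr <- rows - r0
  fc <- cols - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
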