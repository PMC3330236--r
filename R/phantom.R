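#' Specify a pulsating-vessel phantom
#'
#' Bundles and validates the parameters of the synthetic pulsating vessel used
#' to exercise the kinematics and modulus estimators against a known ground
#' truth.  The phantom is a circular lumen whose radius follows a linear
#' (first-order compliance) pressure-radius law, optionally with a pure phase
#' lag between pressure and radius to open the pressure-strain loop into a
#' hysteresis ellipse, as real vessel walls do.
#'
#' Units are fixed throughout: mm, mmHg, seconds.  The default pressure regime
#' (10 +/- 3 mmHg, 1 s period) is a venous one, matching a caval implantation
#' site; the default 8 mm lumen diameter matches a typical scaffold.  Defaults
#' of 30 Hz over 2 s give two full cycles of B-mode-like sampling.
#'
#' @param baseline_radius Lumen radius (mm) at minimum pressure.
#' @param elastic_modulus_true Generating elastic modulus (mmHg per unit
#'   circumferential strain); the downstream estimators should recover it.
#' @param pressure_mean,pressure_amplitude Mean and half-swing of the
#'   sinusoidal intraluminal pressure (mmHg).
#' @param cycle_period Pulsation period (s).
#' @param n_frames Number of imaging frames (>= 4).
#' @param frame_rate Frame rate (Hz).
#' @param contour_points Vertices per lumen contour (>= 8).
#' @param noise_sd_contour SD of i.i.d. radial noise added to each contour
#'   vertex (mm).
#' @param noise_sd_pressure SD of additive noise on pressure samples (mmHg).
#' @param hysteresis_phase_lag Phase lag (radians) of the radius behind the
#'   pressure; 0 gives a closed (degenerate) loop, > 0 an open one.
#' @param seed Integer seed; generation never touches the global RNG state.
#'
#' @return A `vessel_phantom_spec` list.
#' @seealso [generate_phantom()]
#' @export
#' @examples
#' spec <- vessel_phantom_spec(elastic_modulus_true = 50, seed = 1)
#' phantom <- generate_phantom(spec)
#' phantom$ground_truth
vessel_phantom_spec <- function(baseline_radius = 4,
                                elastic_modulus_true = 50,
                                pressure_mean = 10,
                                pressure_amplitude = 3,
                                cycle_period = 1,
                                n_frames = 60,
                                frame_rate = 30,
                                contour_points = 64,
                                noise_sd_contour = 0,
                                noise_sd_pressure = 0,
                                hysteresis_phase_lag = 0,
                                seed = 1L) {
  check_scalar(baseline_radius, "baseline_radius", lower = 0, strict_lower = TRUE)
  check_scalar(elastic_modulus_true, "elastic_modulus_true", lower = 0,
               strict_lower = TRUE)
  check_scalar(pressure_mean, "pressure_mean")
  check_scalar(pressure_amplitude, "pressure_amplitude", lower = 0)
  check_scalar(cycle_period, "cycle_period", lower = 0, strict_lower = TRUE)
  check_scalar(n_frames, "n_frames", lower = 4, integerish = TRUE)
  check_scalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  check_scalar(contour_points, "contour_points", lower = 8, integerish = TRUE)
  check_scalar(noise_sd_contour, "noise_sd_contour", lower = 0)
  check_scalar(noise_sd_pressure, "noise_sd_pressure", lower = 0)
  check_scalar(hysteresis_phase_lag, "hysteresis_phase_lag")
  check_scalar(seed, "seed", integerish = TRUE)
  structure(
    list(
      baseline_radius = baseline_radius,
      elastic_modulus_true = elastic_modulus_true,
      pressure_mean = pressure_mean,
      pressure_amplitude = pressure_amplitude,
      cycle_period = cycle_period,
      n_frames = as.integer(n_frames),
      frame_rate = frame_rate,
      contour_points = as.integer(contour_points),
      noise_sd_contour = noise_sd_contour,
      noise_sd_pressure = noise_sd_pressure,
      hysteresis_phase_lag = hysteresis_phase_lag,
      seed = as.integer(seed)
    ),
    class = "vessel_phantom_spec"
  )
}

#' Generate a pulsating-vessel phantom
#'
#' Simulates the synchronized acquisition an ultrasound + pressure catheter
#' pair would record in a pulsating vessel: per-frame closed lumen contours
#' and an intraluminal pressure trace, plus the analytic ground truth needed
#' to validate every downstream estimator.
#'
#' The construction is
#' \deqn{p(t) = \bar p + A \sin(2\pi t / T)}
#' \deqn{r(t) = r_0 \left(1 + \frac{p(t - \delta) - p_{min}}{E}\right)}
#' where \eqn{\delta} is the phase lag expressed in time and
#' \eqn{p_{min} = \bar p - A}, so the circumferential strain referenced to the
#' minimum-pressure frame is exactly \eqn{(p_{lagged} - p_{min})/E} and its
#' peak is \eqn{2A/E}.  Contour vertices sit on the circle of radius
#' \eqn{r(t)} with i.i.d. radial Gaussian noise.
#'
#' @param spec A [vessel_phantom_spec()].
#' @return A list with:
#'   * `contours`: tibble with columns `frame_index`, `t_seconds`,
#'     `vertex_index`, `x_mm`, `y_mm` (closed contours; the closing edge is
#'     implicit, the first vertex is not repeated);
#'   * `pressure`: tibble with `t_seconds`, `p_mmHg`, sampled 10x faster than
#'     the frames (the pressure catheter is the densely sampled channel);
#'   * `ground_truth`: list echoing `elastic_modulus_true` plus the analytic
#'     noise-free `strain_peak` (= 2 A / E), `radius_by_frame`, and
#'     `strain_by_frame`.
#'
#' Identical spec (including seed) gives identical output.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "vessel_phantom_spec")) {
    va_abort("`spec` must be created by `vessel_phantom_spec()`.",
             "va_validation_error")
  }
  withr::with_seed(spec$seed, {
    t_frames <- (seq_len(spec$n_frames) - 1L) / spec$frame_rate
    omega <- 2 * pi / spec$cycle_period
    lag_time <- spec$hysteresis_phase_lag / omega
    p_min <- spec$pressure_mean - spec$pressure_amplitude

    p_clean <- function(t) {
      spec$pressure_mean + spec$pressure_amplitude * sin(omega * t)
    }
    r_clean <- spec$baseline_radius *
      (1 + (p_clean(t_frames - lag_time) - p_min) / spec$elastic_modulus_true)

    theta <- 2 * pi * (seq_len(spec$contour_points) - 1L) / spec$contour_points
    contours <- purrr::map2_dfr(seq_along(t_frames), r_clean, function(i, r) {
      radii <- r + stats::rnorm(spec$contour_points, 0, spec$noise_sd_contour)
      tibble(
        frame_index = i,
        t_seconds = t_frames[i],
        vertex_index = seq_len(spec$contour_points),
        x_mm = radii * cos(theta),
        y_mm = radii * sin(theta)
      )
    })

    # pressure channel sampled 10x the frame rate over the same span
    t_p <- seq(0, max(t_frames), by = 1 / (10 * spec$frame_rate))
    pressure <- tibble(
      t_seconds = t_p,
      p_mmHg = p_clean(t_p) +
        stats::rnorm(length(t_p), 0, spec$noise_sd_pressure)
    )

    strain_by_frame <- r_clean / spec$baseline_radius - 1
    list(
      contours = contours,
      pressure = pressure,
      ground_truth = list(
        elastic_modulus_true = spec$elastic_modulus_true,
        strain_peak = 2 * spec$pressure_amplitude / spec$elastic_modulus_true,
        radius_by_frame = r_clean,
        strain_by_frame = strain_by_frame,
        t_frames = t_frames
      )
    )
  })
}
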