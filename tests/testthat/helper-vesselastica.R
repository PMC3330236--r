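# shared fixture builders; everything is generated in code

# phantom whose frame grid hits the exact quarter phases of the pressure
# sinusoid, so the diastolic frame sits at the true pressure minimum
quarter_phase_spec <- function(...) {
  vessel_phantom_spec(n_frames = 80, frame_rate = 40, cycle_period = 1, ...)
}

# contour tibble for a circle sampled at n vertices
circle_contour <- function(r, n = 64, cx = 0, cy = 0,
                           frame_index = 1L, t_seconds = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  tibble::tibble(
    frame_index = frame_index,
    t_seconds = t_seconds,
    vertex_index = seq_len(n),
    x_mm = cx + r * cos(th),
    y_mm = cy + r * sin(th)
  )
}

# two-frame contour series from two radii
two_circle_series <- function(r1, r2, n = 64) {
  dplyr::bind_rows(
    circle_contour(r1, n, frame_index = 1L, t_seconds = 0),
    circle_contour(r2, n, frame_index = 2L, t_seconds = 1)
  )
}

# end-to-end modulus recovery on a phantom spec
recover_modulus <- function(spec, method = "loop-fit") {
  ph <- generate_phantom(spec)
  st <- strain_series(ph$contours, "min-pressure", ph$pressure)
  elastic_modulus(build_ps_loop(st, ph$pressure), method = method)$E
}

# exact exponential decay series
exp_series <- function(v0, k, times = 0:5) {
  tibble::tibble(time_weeks = times, value = v0 * exp(-k * times))
}
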