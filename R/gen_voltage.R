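# Synthetic optical voltage maps: a propagating atrial action-potential wave
# sampled by a high-speed camera, with analytic ground-truth activation times.

#' Construct a voltage map object
#'
#' @param data numeric array, frames x rows x cols fluorescence intensities.
#' @param frame_interval_ms sampling period (ms).
#' @param pixel_size_um pixel pitch (micrometres).
#' @param polarity +1 or -1 (sign of the fluorescence deflection on
#'   depolarization).
#' @param valid_mask logical rows x cols matrix of usable pixels.
#' @return object of class `voltage_map`.
#' @export
voltage_map <- function(data, frame_interval_ms, pixel_size_um,
                        polarity = -1, valid_mask = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stopf("`data` must be frames x rows x cols")
  if (dim(data)[1L] < 10L) stopf("voltage map needs >= 10 frames")
  check_scalar_pos(frame_interval_ms, "frame_interval_ms")
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, dim(data)[2L], dim(data)[3L])
  if (!identical(dim(valid_mask), dim(data)[2:3]))
    stopf("`valid_mask` shape must match the spatial shape")
  structure(list(data = data, frame_interval_ms = frame_interval_ms,
                 pixel_size_um = pixel_size_um, polarity = polarity,
                 valid_mask = valid_mask),
            class = "voltage_map")
}

#' @export
print.voltage_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voltage_map> %d frames x %d x %d px, %.3g ms/frame, %.3g um/px, polarity %+d\n",
              d[1L], d[2L], d[3L], x$frame_interval_ms, x$pixel_size_um, x$polarity))
  invisible(x)
}

# Pixel-center coordinates in mm; x runs along columns, y along rows,
# origin at the top-left pixel corner.
pixel_coords_mm <- function(rows, cols, pixel_size_um) {
  px <- pixel_size_um / 1000
  list(x = matrix(rep((seq_len(cols) - 0.5) * px, each = rows), rows, cols),
       y = matrix(rep((seq_len(rows) - 0.5) * px, times = cols), rows, cols))
}

# Analytic activation-time field (ms) for a preset; t0 is the stimulus time.
activation_time_field <- function(preset, t0 = 5) {
  rows <- preset$grid_shape[1L]; cols <- preset$grid_shape[2L]
  cc <- pixel_coords_mm(rows, cols, preset$pixel_size_um)
  v_fast <- preset$cv_cm_per_s / 100           # mm/ms
  th <- preset$fast_axis_deg * pi / 180
  if (preset$geometry == "planar") {
    proj <- cc$x * cos(th) + cc$y * sin(th)
    t_act <- t0 + (proj - min(proj)) / v_fast
  } else if (preset$geometry == "quadratic") {
    # curved front with exactly quadratic activation times: paraxial
    # approximation of a distant point source at 1.5 field-widths
    extent_x <- cols * preset$pixel_size_um / 1000
    y0 <- (rows / 2) * preset$pixel_size_um / 1000
    u <- cc$x * cos(th) + (cc$y - y0) * sin(th)
    w <- -cc$x * sin(th) + (cc$y - y0) * cos(th)
    curv <- 1 / (2 * 1.5 * extent_x * v_fast)
    t_act <- u / v_fast + curv * w^2
    t_act <- t0 + t_act - min(t_act)
  } else {
    v_slow <- v_fast / preset$anisotropy_ratio
    # point stimulus outside the field of view (pacing site is remote from
    # the mapped region); the front inside the field is a gently curved
    # surface that a global quadratic describes well
    extent_x <- cols * preset$pixel_size_um / 1000
    x0 <- -1.5 * extent_x; y0 <- (rows / 2) * preset$pixel_size_um / 1000
    dx <- cc$x - x0; dy <- cc$y - y0
    u <- dx * cos(th) + dy * sin(th)
    w <- -dx * sin(th) + dy * cos(th)
    t_act <- t0 + sqrt((u / v_fast)^2 + (w / v_slow)^2)
  }
  t_act
}

# Logistic steepness for a 10-90% rise time (ms).
logistic_scale_from_rise <- function(rise_ms) rise_ms / (2 * log(9))

#' Generate a synthetic voltage-map movie
#'
#' Each pixel's trace is a logistic upstroke (10-90% rise time 2 ms, mimicking
#' a murine atrial optical action potential) centred at the analytic
#' activation time of a planar or elliptical wave travelling at the preset
#' conduction velocity, followed by repolarization after `apd_ms`. Gaussian
#' noise is added at the preset SNR and the dye polarity applied.
#'
#' @param preset a [wave_preset()].
#' @param seed integer seed; same seed and preset give bit-identical output.
#' @return list with `map` (a [voltage_map()]) and `truth` (class
#'   `ground_truth`: the analytic activation-time field `t_act_ms`, the true
#'   CV vector and scalar, preset and seed).
#' @export
gen_voltage_map <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "wave_preset"))
  dt <- preset$frame_interval_ms
  t_act <- activation_time_field(preset)
  transit <- diff(range(t_act))
  if (transit < 5 * dt)
    stopf("wave crosses the field in %.2f ms < 5 frames; CV unresolvable", transit)
  t_end <- max(t_act) + preset$apd_ms + 10
  n_frames <- max(ceiling(t_end / dt) + 1L, 10L)
  times <- (seq_len(n_frames) - 1L) * dt

  s_up <- logistic_scale_from_rise(2)
  s_rep <- 2
  tt <- outer(times, as.vector(t_act), "-")       # frames x npix
  v <- stats::plogis(tt / s_up) * (1 - stats::plogis((tt - preset$apd_ms) / s_rep))
  f <- 1 + preset$signal_polarity * v
  noise_sd <- if (is.infinite(preset$snr)) 0 else 1 / preset$snr
  f <- with_local_seed(seed, {
    if (noise_sd > 0) f + matrix(stats::rnorm(length(f), 0, noise_sd), nrow(f)) else f
  })
  rows <- preset$grid_shape[1L]; cols <- preset$grid_shape[2L]
  arr <- array(t(f), dim = c(rows, cols, n_frames))
  arr <- aperm(arr, c(3L, 1L, 2L))

  th <- preset$fast_axis_deg * pi / 180
  truth <- structure(list(
    module = "voltage_map", preset = preset, seed = as.integer(seed),
    t_act_ms = t_act,
    cv_cm_per_s = preset$cv_cm_per_s,
    cv_vector_cm_s = preset$cv_cm_per_s * c(cos(th), sin(th)),
    fast_axis_deg = preset$fast_axis_deg,
    noise_sd = noise_sd), class = "ground_truth")
  list(map = voltage_map(arr, dt, preset$pixel_size_um, preset$signal_polarity),
       truth = truth)
}
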