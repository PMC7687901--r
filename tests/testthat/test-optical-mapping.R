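test_that("activation detection finds a noiseless logistic upstroke at 30 ms", {
  t <- (0:59) * 1
  s <- 2 / (2 * log(9))
  up <- plogis((t - 30) / s) * (1 - plogis((t - 30 - 25) / 2))
  arr <- array(rep(1 - up, times = 16), c(60, 4, 4))  # polarity -1 traces
  arr <- aperm(array(rep(1 - up, each = 1), c(60, 4, 4)), c(1, 2, 3))
  for (i in 1:4) for (j in 1:4) arr[, i, j] <- 1 - up
  map <- voltage_map(arr, 1, 100, polarity = -1)
  act <- detect_activation_times(map)
  expect_true(all(abs(act$t_act_ms - 30) <= 0.5))
})

test_that("flat and low-SNR traces are masked; all-flat map fails explicitly", {
  set.seed(42)
  t <- (0:59)
  up <- plogis((t - 30) / 0.455)
  arr <- array(0, c(60, 2, 2))
  arr[, 1, 1] <- 1 - up
  arr[, 1, 2] <- 1 - up
  arr[, 2, 1] <- 1                      # flat
  arr[, 2, 2] <- 1 + rnorm(60, 0, 0.2)  # pure noise
  map <- voltage_map(arr, 1, 100, polarity = -1)
  act <- detect_activation_times(map, snr_min = 5)
  expect_true(act$mask[1, 1] && act$mask[1, 2])
  expect_false(act$mask[2, 1])
  expect_false(act$mask[2, 2])
  flat <- voltage_map(array(1, c(20, 3, 3)), 1, 100)
  expect_error(detect_activation_times(flat), "no activations")
})

test_that("activation detection tracks generator truth at SNR 20 within one frame RMS", {
  g <- gen_voltage_map(small_wave(cv_cm_per_s = 21, snr = 20), seed = 1)
  act <- detect_activation_times(g$map)
  err <- act$t_act_ms - g$truth$t_act_ms
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 1)
  expect_gt(mean(act$mask), 0.95)
})

test_that("quadratic surface fit is exact on polynomial fields", {
  px <- 1000  # 1 mm pixels for easy coordinates
  cc <- idnano:::pixel_coords_mm(8, 8, px)
  # planar: T = 5x
  act <- act_map_from_matrix(5 * cc$x, pixel_size_um = px)
  s <- fit_activation_surface(act)
  expect_equal(unname(coef(s)), c(0, 0, 0, 5, 0, 0), tolerance = 1e-9)
  expect_lt(s$residual_rms_ms, 1e-9)
  # curved: T = x^2 + y^2
  act2 <- act_map_from_matrix(cc$x^2 + cc$y^2, pixel_size_um = px)
  s2 <- fit_activation_surface(act2)
  expect_equal(unname(coef(s2)), c(1, 1, 0, 0, 0, 0), tolerance = 1e-9)
})

test_that("surface fit on noisy planar truth is unbiased over a seed sweep", {
  px <- 1000
  cc <- idnano:::pixel_coords_mm(10, 10, px)
  d_hat <- vapply(1:20, function(s) {
    set.seed(s)
    act <- act_map_from_matrix(5 * cc$x + rnorm(100, 0, 0.5), pixel_size_um = px)
    unname(coef(fit_activation_surface(act))["d"])
  }, numeric(1))
  se <- sd(d_hat) / sqrt(20)
  expect_lt(abs(mean(d_hat) - 5), 3 * se + 1e-8)
})

test_that("degenerate fit geometries are rejected", {
  m <- matrix(NA_real_, 6, 6); m[1, ] <- 1:6
  act <- act_map_from_matrix(m)
  act$mask <- !is.na(m)
  expect_error(fit_activation_surface(act), "rank-deficient|degenerate")
  act$mask[] <- FALSE
  expect_error(fit_activation_surface(act), ">= 6")
})

test_that("velocity field inverts slowness: grad T (5,0) ms/mm gives 20 cm/s", {
  px <- 1000
  cc <- idnano:::pixel_coords_mm(8, 8, px)
  act <- act_map_from_matrix(5 * cc$x, pixel_size_um = px)
  s <- fit_activation_surface(act)
  f <- velocity_field(s, act)
  expect_equal(f$vx[act$mask], rep(20, 64), tolerance = 1e-9)
  expect_equal(f$vy[act$mask], rep(0, 64), tolerance = 1e-9)
  # radial field points outward
  act2 <- act_map_from_matrix(cc$x^2 + cc$y^2, pixel_size_um = px)
  s2 <- fit_activation_surface(act2)
  f2 <- velocity_field(s2, act2)
  dot <- f2$vx * cc$x + f2$vy * cc$y
  expect_true(all(dot[f2$mask] > 0))
})

test_that("velocity-slowness identity v . grad T = 1 on noiseless fits", {
  g <- gen_voltage_map(small_wave(cv_cm_per_s = 18, snr = Inf,
                                  geometry = "elliptical"), seed = 1)
  act <- detect_activation_times(g$map)
  s <- fit_activation_surface(act)
  f <- velocity_field(s, act)
  cc <- idnano:::pixel_coords_mm(nrow(act$mask), ncol(act$mask), act$pixel_size_um)
  gr <- predict(s, cc$x, cc$y, gradient = TRUE)
  dot <- (f$vx / 100) * gr$gx + (f$vy / 100) * gr$gy  # cm/s -> mm/ms
  expect_equal(dot[f$mask], rep(1, sum(f$mask)), tolerance = 1e-9)
})

test_that("pixelwise speed matches the analytic gradient on a noiseless curved front", {
  p <- small_wave(cv_cm_per_s = 20, snr = Inf, geometry = "quadratic")
  g <- gen_voltage_map(p, seed = 1)
  act <- detect_activation_times(g$map)
  s <- fit_activation_surface(act)
  f <- velocity_field(s, act)
  # analytic slowness of the quadratic wave at each pixel
  cc <- idnano:::pixel_coords_mm(nrow(act$mask), ncol(act$mask), p$pixel_size_um)
  vf <- p$cv_cm_per_s / 100
  extent_x <- ncol(act$mask) * p$pixel_size_um / 1000
  y0 <- nrow(act$mask) / 2 * p$pixel_size_um / 1000
  w <- cc$y - y0
  curv <- 1 / (2 * 1.5 * extent_x * vf)
  slow <- sqrt((1 / vf)^2 + (2 * curv * w)^2)
  speed_true <- 100 / slow
  rel <- abs(f$speed - speed_true) / speed_true
  expect_lt(max(rel[f$mask]), 0.02)
})

test_that("fast-axis CV: uniform field, forced-axis failure, wedge bookkeeping", {
  px <- 1000
  cc <- idnano:::pixel_coords_mm(8, 8, px)
  act <- act_map_from_matrix(5 * cc$x, pixel_size_um = px)
  s <- fit_activation_surface(act)
  f <- velocity_field(s, act)
  cv <- conduction_velocity(f)
  expect_equal(cv$cv_cm_per_s, 20, tolerance = 1e-9)
  expect_lt(abs(cv$fast_axis_deg), 5)
  expect_identical(cv$n_vectors_used, 64L)
  # all vectors at 90 deg but axis forced to 0: insufficient data
  act2 <- act_map_from_matrix(5 * cc$y, pixel_size_um = px)
  f2 <- velocity_field(fit_activation_surface(act2), act2)
  expect_error(conduction_velocity(f2, fast_axis_deg = 0), "insufficient")
})

test_that("noiseless planar CV is exact to 0.5% and rotation-invariant", {
  p <- small_wave(cv_cm_per_s = 20, snr = Inf)
  g <- gen_voltage_map(p, seed = 1)
  cv <- map_conduction_velocity(g$map)
  expect_lt(abs(cv$cv_cm_per_s - 20) / 20, 0.005)
  # rotate the movie by 90 degrees: magnitude unchanged within 1%
  arr <- g$map$data
  rot <- array(0, c(dim(arr)[1], dim(arr)[3], dim(arr)[2]))
  for (k in seq_len(dim(arr)[1])) rot[k, , ] <- t(arr[k, dim(arr)[2]:1, ])
  cv_rot <- map_conduction_velocity(voltage_map(rot, 1, p$pixel_size_um, -1))
  expect_lt(abs(cv_rot$cv_cm_per_s - cv$cv_cm_per_s) / cv$cv_cm_per_s, 0.01)
})

test_that("CV recovery degrades monotonically as SNR falls", {
  snrs <- c(40, 10, 5)
  err <- vapply(snrs, function(sn) {
    e <- vapply(1:5, function(s) {
      g <- gen_voltage_map(small_wave(cv_cm_per_s = 20, snr = sn), seed = s)
      cv <- map_conduction_velocity(g$map, snr_min = 3, fast_axis_deg = 0)
      abs(cv$cv_cm_per_s - 20)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(err) >= -1e-6))
})

test_that("isochrones: planar waves give parallel equispaced lines, masked regions none", {
  px <- 1000
  cc <- idnano:::pixel_coords_mm(12, 12, px)
  act <- act_map_from_matrix(5 * cc$x, pixel_size_um = px)
  iso <- isochrone_map(act, step_ms = 5)
  expect_gt(length(iso$lines), 5)
  for (l in iso$lines) expect_lt(diff(range(l$x)), 1e-6)  # vertical lines
  xs <- sort(vapply(iso$lines, function(l) l$x[1], numeric(1)))
  expect_equal(diff(xs), rep(1, length(xs) - 1), tolerance = 1e-6)
  # radial: concentric rings (every contour point equidistant from origin)
  act2 <- act_map_from_matrix(cc$x^2 + cc$y^2, pixel_size_um = px)
  iso2 <- isochrone_map(act2, step_ms = 20)
  for (l in iso2$lines) {
    r <- sqrt(l$x^2 + l$y^2)
    expect_lt(diff(range(r)) / mean(r), 0.05)
  }
  # masked half: no contours there
  act3 <- act_map_from_matrix(5 * cc$x, pixel_size_um = px)
  act3$mask[, 7:12] <- FALSE
  act3$t_act_ms[, 7:12] <- NA
  iso3 <- isochrone_map(act3, step_ms = 5)
  all_x <- unlist(lapply(iso3$lines, function(l) l$x))
  expect_true(all(all_x <= 6.5))
})
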