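test_that("generators are bit-deterministic given seed + preset", {
  a <- gen_voltage_map(small_wave(), seed = 9)
  b <- gen_voltage_map(small_wave(), seed = 9)
  expect_identical(a$map$data, b$map$data)
  c <- gen_voltage_map(small_wave(), seed = 10)
  expect_false(identical(a$map$data, c$map$data))

  e1 <- gen_ecg_trace(ecg_preset(observation_s = 5), seed = 3)
  e2 <- gen_ecg_trace(ecg_preset(observation_s = 5), seed = 3)
  expect_identical(e1$trace$samples, e2$trace$samples)

  p <- id_cloud_preset(n_target_molecules = 500L)
  s1 <- gen_id_point_cloud(p, seed = 5)
  s2 <- gen_id_point_cloud(p, seed = 5)
  expect_identical(s1$table$x_nm, s2$table$x_nm)
  expect_identical(s1$truth$labels, s2$truth$labels)
})

test_that("generators do not disturb the session RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_voltage_map(small_wave(), seed = 4)); after <- runif(1)
  expect_identical(before, after)
})

test_that("planar wave kinematics: 20 cm/s gives 5 ms/mm slowness", {
  p <- small_wave(cv_cm_per_s = 20, fast_axis_deg = 0, snr = Inf)
  g <- gen_voltage_map(p, seed = 1)
  tr <- g$truth$t_act_ms
  # pixels are 100 um: 10 columns = 1 mm
  expect_equal(tr[1, 11] - tr[1, 1], 5, tolerance = 1e-12)
  expect_equal(tr[5, 1], tr[20, 1], tolerance = 1e-12)  # no gradient across rows
})

test_that("noiseless curved-front truth equals the analytic field to machine precision", {
  p <- small_wave(cv_cm_per_s = 15, snr = Inf, geometry = "elliptical",
                  anisotropy_ratio = 2)
  g <- gen_voltage_map(p, seed = 2)
  tf <- idnano:::activation_time_field(p)
  expect_equal(g$truth$t_act_ms, tf, tolerance = 1e-15)
})

test_that("voltage-map noise is zero-mean at the preset SNR", {
  p0 <- small_wave(snr = Inf); pn <- small_wave(snr = 10)
  g0 <- gen_voltage_map(p0, seed = 7)$map$data
  gn <- gen_voltage_map(pn, seed = 7)$map$data
  resid <- gn - g0
  expect_lt(abs(mean(resid)), 3 * 0.1 / sqrt(length(resid)))
  expect_equal(sd(resid), 0.1, tolerance = 0.02)
})

test_that("grids where the wave is unresolvable are rejected", {
  expect_error(wave_preset(cv_cm_per_s = 500, grid_shape = c(8L, 8L)),
               "transit")
})

test_that("ECG ground truth: burden arithmetic and episode constraints", {
  p <- ecg_preset(observation_s = 60, episodes = list(c(10, 5)))
  g <- gen_ecg_trace(p, seed = 1)
  expect_equal(g$truth$burden_s_per_h, 300)  # 5/60 * 3600
  expect_error(ecg_preset(episodes = list(c(10, 5), c(12, 5))), "overlap")
  expect_error(ecg_preset(episodes = list(c(58, 5))), "within")
  expect_error(ecg_preset(p_duration_ms = 45, pr_ms = 40), "pr_ms")
})

test_that("episode deflections are irregular (interval CV > 0.2) and span the episode", {
  g <- gen_ecg_trace(ecg_preset(observation_s = 30, episodes = list(c(10, 8)),
                                noise_sd_mv = 0), seed = 6)
  tims <- g$truth$episode_deflection_times_s[[1]]
  iv <- diff(tims)
  expect_gt(sd(iv) / mean(iv), 0.2)
  expect_equal(tims[1], 10)
  expect_equal(tims[length(tims)], 18)
  # roughly twice the sinus rate
  expect_lt(mean(iv), 60 / 450 / 1.5)
})

test_that("point-cloud labels hit the preset fractions within binomial error", {
  p <- id_cloud_preset(frac_near_gj = 0.59, frac_near_mj = 0.35,
                       n_target_molecules = 10000L)
  g <- gen_id_point_cloud(p, seed = 7)
  se <- sqrt(0.59 * 0.41 / 10000)
  expect_lt(abs(g$truth$frac_near_gj - 0.59), 4 * se)
  expect_lt(abs(g$truth$frac_near_mj - 0.35), 4 * sqrt(0.35 * 0.65 / 10000))
  # labels are the geometric truth of the emitted coordinates
  gj <- idnano:::loc_coords(g$table, "Cx43")
  tgt <- idnano:::loc_coords(g$table, "NaV1.5")
  d <- idnano:::min_dist_to_set(tgt, gj)
  expect_identical(unname(d <= 100), g$truth$labels == 1L)
})

test_that("degenerate point-cloud presets behave", {
  # frac 1, no jitter: every target within the shell
  p <- id_cloud_preset(frac_near_gj = 1, frac_near_mj = 0,
                       n_target_molecules = 300L,
                       loc_precision_xy_nm = 0, loc_precision_z_nm = 0)
  g <- gen_id_point_cloud(p, seed = 3)
  gj <- idnano:::loc_coords(g$table, "Cx43")
  tgt <- idnano:::loc_coords(g$table, "NaV1.5")
  expect_true(all(idnano:::min_dist_to_set(tgt, gj) <= 100))
  # zero molecules: empty target channel, valid truth
  p0 <- id_cloud_preset(n_target_molecules = 0L)
  g0 <- gen_id_point_cloud(p0, seed = 1)
  expect_identical(sum(g0$table$channel == "NaV1.5"), 0L)
  expect_identical(length(g0$truth$labels), 0L)
  # field too small for disjoint halves
  expect_error(id_cloud_preset(field_nm = c(500, 500, 300)), "too small")
})

test_that("membrane pair generator matches its analytic gap profile", {
  g <- gen_membrane_pair(membrane_preset(mean_gap_nm = 17, gap_waviness_nm = 0,
                                         n_vertices = 80L), seed = 1)
  expect_identical(nrow(g$pair$trace_a), 80L)
  gaps <- g$pair$trace_b[, 2] - g$pair$trace_a[, 2]
  expect_equal(gaps, rep(17, 80))
  g2 <- gen_membrane_pair(membrane_preset(mean_gap_nm = 64, gap_waviness_nm = 5),
                          seed = 1)
  expect_equal(mean(g2$truth$gap_nm), 64, tolerance = 1e-3)  # sine integrates out
  expect_error(membrane_preset(mean_gap_nm = 10, gap_waviness_nm = 12),
               "waviness")
})

test_that("voxel rendering conserves intensity and localizes single molecules", {
  tab <- localization_table(500, 400, 300, "NaV1.5")
  img <- render_voxel_image(tab, psf_sigma_nm = c(30, 30, 40),
                            voxel_nm = c(25, 25, 25))
  arr <- img$channels$NaV1.5
  expect_equal(sum(arr), 1, tolerance = 0.01)
  mx <- arrayInd(which.max(arr), dim(arr))
  org <- attr(img, "origin_nm")
  expect_equal(as.numeric((mx - 0.5) * 25 + org), c(500, 400, 300), tolerance = 25)

  # empty table: all-zero image on an explicit field
  e <- render_voxel_image(localization_table(numeric(0), numeric(0), numeric(0),
                                             character(0)),
                          field_nm = c(200, 200, 200), origin_nm = c(0, 0, 0))
  expect_true(all(e$channels[[1]] == 0))

  # 100 interior molecules: total intensity within 1% of the analytic kernel sum
  set.seed(8)
  n <- 100
  tab2 <- localization_table(runif(n, 300, 700), runif(n, 300, 700),
                             runif(n, 300, 700), rep("Cx43", n))
  img2 <- render_voxel_image(tab2, psf_sigma_nm = c(30, 30, 40),
                             voxel_nm = c(25, 25, 25))
  expect_equal(sum(img2$channels$Cx43), n, tolerance = 0.01)
  # out-of-field molecules are dropped with a message
  tab3 <- localization_table(c(100, 5000), c(100, 100), c(100, 100),
                             rep("Cx43", 2))
  expect_message(img3 <- render_voxel_image(tab3, field_nm = c(300, 300, 300),
                                            origin_nm = c(0, 0, 0)),
                 "dropped 1")
  expect_identical(attr(img3, "n_dropped"), 1L)
})
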