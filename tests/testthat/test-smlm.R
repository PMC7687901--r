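test_that("clustering separates well-separated blobs and matches the graph oracle", {
  # two blobs 1 um apart -> exactly 2 clusters
  tab <- blob_table(rbind(c(0, 0, 0), c(1000, 0, 0)), n_per = 100, sigma = 20,
                    seed = 1)
  cs <- cluster_localizations(tab, "Cx43", eps_nm = 50, min_pts = 5)
  expect_identical(length(cs$clusters), 2L)
  expect_identical(cs$n_unclustered, 0L)

  # k = 20 blobs on a grid: 20 clusters, labels equal eps-graph components
  centers <- as.matrix(expand.grid(x = (0:4) * 800, y = (0:3) * 800, z = 0))
  tab20 <- blob_table(centers, n_per = 60, sigma = 15, seed = 2)
  cs20 <- cluster_localizations(tab20, "Cx43", eps_nm = 60, min_pts = 5)
  expect_identical(length(cs20$clusters), 20L)
  pts <- idnano:::loc_coords(tab20)
  pts_scaled <- pts  # precision ratio is 1 in blob_table
  oracle <- graph_components_oracle(pts_scaled, 60)
  # same partition up to label permutation
  expect_identical(length(unique(oracle)), 20L)
  tab_lab <- table(cs20$labels, oracle)
  expect_true(all(rowSums(tab_lab > 0) == 1) && all(colSums(tab_lab > 0) == 1))

  # empty channel -> empty set, not an error
  e <- cluster_localizations(tab, "N-cad")
  expect_identical(length(e$clusters), 0L)
})

test_that("clustering rescales z by the precision ratio before distances", {
  # two points 100 nm apart along z only; eps 50: separate in raw units,
  # together once z is compressed by precision_z/precision_xy = 2.5
  tab <- localization_table(c(0, 0), c(0, 0), c(0, 100), rep("Cx43", 2),
                            precision_xy_nm = 20, precision_z_nm = 50)
  cs <- cluster_localizations(tab, "Cx43", eps_nm = 50, min_pts = 2)
  expect_identical(length(cs$clusters), 1L)
  tab2 <- localization_table(c(0, 0), c(0, 0), c(0, 100), rep("Cx43", 2),
                             precision_xy_nm = 20, precision_z_nm = 20)
  cs2 <- cluster_localizations(tab2, "Cx43", eps_nm = 50, min_pts = 2)
  expect_identical(length(cs2$clusters), 0L)
})

test_that("nearest-reference distance equals brute force exactly", {
  g <- gen_id_point_cloud(id_cloud_preset(n_target_molecules = 500L), seed = 4)
  refs <- cluster_localizations(g$table, "Cx43")
  tgt <- g$table[g$table$channel == "NaV1.5", ]
  d <- nearest_reference_distance(tgt, refs)
  oracle <- brute_min_dist(idnano:::loc_coords(tgt),
                           refs$points[refs$labels > 0, , drop = FALSE])
  expect_equal(d, oracle, tolerance = 1e-12)

  # 3-4-5 triangle: single ref cluster at the origin, target at (60, 80, 0)
  ref1 <- localization_table(rep(0, 5), rep(0, 5), rep(0, 5), rep("Cx43", 5))
  cs1 <- cluster_localizations(ref1, "Cx43", eps_nm = 10, min_pts = 3)
  d1 <- nearest_reference_distance(matrix(c(60, 80, 0), 1), cs1)
  expect_equal(d1, 100, tolerance = 1e-12)
  # coincident target: distance 0
  expect_equal(nearest_reference_distance(matrix(c(0, 0, 0), 1), cs1), 0)
  # no reference clusters: explicit failure
  empty <- cluster_localizations(ref1, "N-cad")
  expect_error(nearest_reference_distance(matrix(0, 1, 3), empty),
               "no reference clusters")
})

test_that("fraction_within: trivial extremes, monotonicity, empty flag", {
  ref <- blob_table(matrix(c(0, 0, 0), 1), n_per = 50, sigma = 15, seed = 3)
  refs <- cluster_localizations(ref, "Cx43")
  near <- sweep(matrix(rnorm(90, 0, 10), 30, 3), 2, c(0, 0, 0), "+")
  far <- sweep(matrix(rnorm(90, 0, 10), 30, 3), 2, c(5000, 0, 0), "+")
  expect_equal(fraction_within(near, refs), 100)
  expect_equal(fraction_within(far, refs), 0)
  mix <- rbind(near, far)
  shells <- c(50, 100, 200, 1000, 6000)
  fr <- vapply(shells, function(s) fraction_within(mix, refs, s), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_warning(f0 <- fraction_within(matrix(numeric(0), 0, 3), refs),
                 "undefined")
  expect_true(is.na(f0))
})

test_that("preset fractions are recovered by the analysis within tolerance", {
  est <- tru <- numeric(6)
  for (s in 1:6) {
    g <- gen_id_point_cloud(id_cloud_preset(frac_near_gj = 0.59,
                                            frac_near_mj = 0.35), seed = s)
    refs <- cluster_localizations(g$table, "Cx43")
    est[s] <- fraction_within(g$table[g$table$channel == "NaV1.5", ], refs)
    tru[s] <- 100 * g$truth$frac_near_gj
  }
  expect_lt(abs(mean(est) - 59), 2)
  expect_lt(mean(abs(est - tru)), 2)
})

test_that("enrichment ratio: uniform Poisson gives 1, zero-complement flagged", {
  g <- gen_id_point_cloud(id_cloud_preset(uniform_targets = TRUE,
                                          n_target_molecules = 8000L), seed = 2)
  refs <- cluster_localizations(g$table, "Cx43")
  er <- enrichment_ratio(g$table[g$table$channel == "NaV1.5", ], refs, g$table,
                         mc_samples = 4e4)
  expect_lt(abs(er$ratio - 1), 0.1)
  # all targets inside the shell: outside density zero -> NA, flagged
  ref <- blob_table(matrix(c(0, 0, 0), 1), n_per = 60, sigma = 15, seed = 5)
  refs2 <- cluster_localizations(ref, "Cx43")
  near <- matrix(rnorm(150, 0, 10), 50, 3)
  expect_warning(er2 <- enrichment_ratio(near, refs2, rbind(idnano:::loc_coords(ref), near),
                                         mc_samples = 2e4),
                 "undefined")
  expect_true(is.na(er2$ratio))
})

test_that("constructed density ratios are recovered within 15%", {
  for (rho in c(5, 10)) {
    g <- gen_id_point_cloud(id_cloud_preset(density_ratio_gj = rho,
                                            density_ratio_mj = 1), seed = rho)
    refs <- cluster_localizations(g$table, "Cx43")
    er <- enrichment_ratio(g$table[g$table$channel == "NaV1.5", ], refs,
                           g$table, mc_samples = 5e4)
    expect_lt(abs(er$ratio / g$truth$density_ratio_gj - 1), 0.15)
  }
})

test_that("results are invariant under rigid transforms of all coordinates", {
  g <- gen_id_point_cloud(id_cloud_preset(n_target_molecules = 2000L), seed = 9)
  tab <- g$table
  refs <- cluster_localizations(tab, "Cx43")
  tgt <- tab[tab$channel == "NaV1.5", ]
  f0 <- fraction_within(tgt, refs)
  d0 <- nearest_reference_distance(tgt, refs)
  # rotate about z by 33 degrees and translate
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  p <- idnano:::loc_coords(tab) %*% t(R)
  tab2 <- localization_table(p[, 1] + 5000, p[, 2] - 2000, p[, 3] + 300,
                             tab$channel, tab$precision_xy_nm, tab$precision_z_nm)
  refs2 <- cluster_localizations(tab2, "Cx43")
  tgt2 <- tab2[tab2$channel == "NaV1.5", ]
  expect_equal(fraction_within(tgt2, refs2), f0, tolerance = 1e-12)
  expect_equal(nearest_reference_distance(tgt2, refs2), d0, tolerance = 1e-9)
})

test_that("bivariate histogram: placement, totals, and marginalization", {
  ref <- blob_table(matrix(c(0, 0, 0), 1), n_per = 60, sigma = 15, seed = 6)
  refs <- cluster_localizations(ref, "Cx43")
  centers <- rbind(c(300, 0, 0), c(800, 0, 0), c(1500, 0, 0))
  tgt <- blob_table(centers, n_per = 50, sigma = 15, channel = "NaV1.5", seed = 7)
  cl <- cluster_localizations(tgt, "NaV1.5")
  expect_identical(length(cl$clusters), 3L)
  de <- seq(0, 2000, by = 250)
  ve <- c(0, 10^seq(-6, 0, by = 1))
  bh <- bivariate_histogram(cl, refs, de, ve, value = "density")
  expect_identical(sum(bh$counts), 3L)
  # marginal over value = 1D histogram of distances computed independently
  cen <- do.call(rbind, lapply(cl$clusters, function(c) c$centroid))
  d <- brute_min_dist(cen, refs$points[refs$labels > 0, ])
  h1 <- hist(d, breaks = de, plot = FALSE)$counts
  expect_identical(as.integer(rowSums(bh$counts)), as.integer(h1))
  # single known cluster lands in the right cell
  one <- blob_table(matrix(c(600, 0, 0), 1), n_per = 50, sigma = 10,
                    channel = "NaV1.5", seed = 8)
  cl1 <- cluster_localizations(one, "NaV1.5")
  bh1 <- bivariate_histogram(cl1, refs, de, c(0, 100), value = "count")
  d1 <- brute_min_dist(matrix(cl1$clusters[[1]]$centroid, 1),
                       refs$points[refs$labels > 0, ])
  expect_identical(sum(bh1$counts), 1L)
  expect_identical(which(rowSums(bh1$counts) == 1L), findInterval(d1, de))
})

test_that("cluster attributes: density = count / hull volume for >= 4 points", {
  tab <- blob_table(matrix(c(0, 0, 0), 1), n_per = 80, sigma = 25, seed = 10)
  cs <- cluster_localizations(tab, "Cx43")
  cl <- cs$clusters[[1]]
  expect_equal(cl$density, cl$count / cl$volume_nm3)
  expect_equal(cl$volume_nm3,
               idnano:::hull_volume(cs$points[cl$members, ]), tolerance = 1e-9)
  # 3-point cluster: volume 0, density undefined
  t3 <- localization_table(c(0, 10, 20), c(0, 5, 0), c(0, 0, 5), rep("Cx43", 3))
  c3 <- cluster_localizations(t3, "Cx43", eps_nm = 50, min_pts = 3)
  expect_identical(c3$clusters[[1]]$volume_nm3, 0)
  expect_true(is.na(c3$clusters[[1]]$density))
})
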