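# Independent oracles and small fixture builders used across the suite.

# brute-force O(n^2) minimum distance from each row of a to the rows of b
brute_min_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    sqrt(min(colSums((t(b) - a[i, ])^2))), numeric(1))
}

# connected components of the eps-distance graph by label propagation
# (no igraph, no grid): the oracle for clustering on dense, all-core scenes
graph_components_oracle <- function(pts, eps) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  adj <- d <= eps
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(labels[adj[i, ]])
      if (m < labels[i]) { labels[i] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# stack-based flood fill labeling of foreground voxels, 26-connectivity
flood_fill_oracle <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  fg <- which(mask)
  for (start in fg) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      co <- arrayInd(v, dims)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1L) || any(nb > dims)) next
        lin <- (nb[3L] - 1L) * dims[1L] * dims[2L] + (nb[2L] - 1L) * dims[1L] + nb[1L]
        if (mask[lin] && labels[lin] == 0L) { labels[lin] <- cur; stack <- c(stack, lin) }
      }
    }
  }
  labels
}

# full enumeration of 2x2 tables with the observed margins; two-sided
# Fisher p = sum of hypergeometric probabilities <= observed probability
fisher_enumeration_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# build an activation_map directly from a matrix of times (all unmasked)
act_map_from_matrix <- function(t_mat, pixel_size_um = 100, frame_interval_ms = 1) {
  structure(list(t_act_ms = t_mat,
                 mask = matrix(TRUE, nrow(t_mat), ncol(t_mat)),
                 snr = matrix(Inf, nrow(t_mat), ncol(t_mat)),
                 frame_interval_ms = frame_interval_ms,
                 pixel_size_um = pixel_size_um),
            class = "activation_map")
}

# localization table of k Gaussian blobs at given 3D centres
blob_table <- function(centers, n_per = 100, sigma = 20, channel = "Cx43",
                       seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(stats::rnorm(3 * n_per, 0, sigma), n_per, 3), 2, centers[i, ], "+")))
  localization_table(pts[, 1], pts[, 2], pts[, 3],
                     rep(channel, nrow(pts)), 20, 20)
}

# small fast presets
small_wave <- function(...) wave_preset(grid_shape = c(24L, 24L), ...)

# blob scene: one Cx43 reference blob, `near_n` target blobs on a 120 nm
# circle around it and `far_n` target blobs 1.5 um away; returns the
# localization table and its rendering
mk_blob_scene <- function(near_n, far_n) {
  ref <- data.frame(x = rnorm(60, 1000, 30), y = rnorm(60, 500, 30),
                    z = rnorm(60, 250, 30))
  ang <- 2 * pi * (seq_len(near_n) - 1) / max(near_n, 1)
  near <- do.call(rbind, lapply(seq_len(near_n), function(i)
    data.frame(x = rnorm(60, 1000 + 120 * cos(ang[i]), 25),
               y = rnorm(60, 500 + 120 * sin(ang[i]), 25),
               z = rnorm(60, 250, 25))))
  far <- do.call(rbind, lapply(seq_len(far_n), function(i)
    data.frame(x = rnorm(60, 2500, 25), y = rnorm(60, 300 + i * 250, 25),
               z = rnorm(60, 250, 25))))
  tgt <- rbind(near, far)
  tab <- localization_table(c(ref$x, tgt$x), c(ref$y, tgt$y), c(ref$z, tgt$z),
                            c(rep("Cx43", nrow(ref)), rep("NaV1.5", nrow(tgt))))
  img <- render_voxel_image(tab, psf_sigma_nm = c(30, 30, 40),
                            voxel_nm = c(25, 25, 50),
                            field_nm = c(3000, 1500, 500),
                            origin_nm = c(0, 0, 0))
  list(table = tab, image = img)
}
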