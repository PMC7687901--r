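# STORM-style cluster enrichment analysis: density-reachability clustering of
# localization tables, nearest-reference (cluster-edge) distances, fraction
# of target signal within the 100 nm proximity shell, density enrichment
# ratios over the ID region, and bivariate distance/value histograms.

# Grid-accelerated DBSCAN. pts: n x 3 matrix (already scaled), eps radius,
# min_pts: minimum neighbourhood size (including the point itself) for a core
# point. Returns integer labels (0 = noise), deterministic in row order.
dbscan_points <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  cell <- floor(sweep(pts, 2L, apply(pts, 2L, min)) / eps)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  by_cell <- split(seq_len(n), key)
  cell_of <- match(key, names(by_cell))
  # neighbour cells (27-neighbourhood) per cell key
  ckey <- do.call(rbind, strsplit(names(by_cell), " "))
  storage.mode(ckey) <- "double"
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb_of_cell <- lapply(seq_len(nrow(ckey)), function(ci) {
    nk <- paste(ckey[ci, 1L] + offs[, 1L], ckey[ci, 2L] + offs[, 2L], ckey[ci, 3L] + offs[, 3L])
    unlist(by_cell[nk[nk %in% names(by_cell)]], use.names = FALSE)
  })
  eps2 <- eps^2
  neighbors <- function(i) {
    cand <- nb_of_cell[[cell_of[i]]]
    d2 <- (pts[cand, 1L] - pts[i, 1L])^2 + (pts[cand, 2L] - pts[i, 2L])^2 +
          (pts[cand, 3L] - pts[i, 3L])^2
    cand[d2 <= eps2]
  }
  nbr <- lapply(seq_len(n), neighbors)
  core <- lengths(nbr) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbr[[i]]
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbr[[j]][labels[nbr[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster localizations of one channel
#'
#' Density-reachability clustering (points with at least `min_pts` neighbours
#' within `eps_nm` are core; clusters are the sets of density-connected
#' points; remaining points are reported as unclustered). Before distance
#' computation, z is rescaled by the lateral/axial precision ratio so the
#' neighbourhood is isotropic in units of localization precision; all
#' reported cluster attributes use raw nm coordinates.
#'
#' @param table a [localization_table()].
#' @param channel channel to cluster.
#' @param eps_nm neighbourhood radius (nm), default 50.
#' @param min_pts core-point threshold (neighbours within `eps_nm`,
#'   including the point itself), default 5.
#' @return object of class `cluster_set`: per-cluster member indices (rows of
#'   the channel subset), centroid, convex-hull volume (nm^3), count, and
#'   density (count/nm^3, `NA` for clusters with fewer than 4 points, which
#'   carry volume 0); plus the channel points, labels, and unclustered count.
#' @export
cluster_localizations <- function(table, channel, eps_nm = 50, min_pts = 5L) {
  stopifnot(inherits(table, "localization_table"))
  sub <- table[table$channel == channel, , drop = FALSE]
  pts <- as.matrix(sub[, c("x_nm", "y_nm", "z_nm")])
  if (nrow(pts) == 0L) {
    return(structure(list(channel = channel, points = pts, labels = integer(0),
                          clusters = list(), n_unclustered = 0L,
                          eps_nm = eps_nm, min_pts = min_pts),
                     class = "cluster_set"))
  }
  zs <- stats::median(sub$precision_z_nm) / stats::median(sub$precision_xy_nm)
  scaled <- pts
  scaled[, 3L] <- scaled[, 3L] / max(zs, 1e-9)
  labels <- dbscan_points(scaled, eps_nm, min_pts)
  clusters <- lapply(seq_len(max(labels, 0L)), function(k) {
    idx <- which(labels == k)
    p <- pts[idx, , drop = FALSE]
    vol <- if (length(idx) >= 4L) hull_volume(p) else 0
    list(members = idx, centroid = colMeans(p), count = length(idx),
         volume_nm3 = vol,
         density = if (vol > 0) length(idx) / vol else NA_real_)
  })
  structure(list(channel = channel, points = pts, labels = labels,
                 clusters = clusters, n_unclustered = sum(labels == 0L),
                 eps_nm = eps_nm, min_pts = min_pts),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> channel %s: %d clusters from %d localizations (%d unclustered); eps %g nm, min_pts %d\n",
              x$channel, length(x$clusters), nrow(x$points), x$n_unclustered,
              x$eps_nm, x$min_pts))
  invisible(x)
}

# All clustered member coordinates of a cluster_set (raw nm).
clustered_points <- function(refs) {
  if (!length(refs$clusters)) stopf("no reference clusters: cannot measure proximity")
  refs$points[refs$labels > 0L, , drop = FALSE]
}

#' Distance from each target molecule to the nearest reference cluster edge
#'
#' Euclidean distance (raw nm) from each target molecule to the nearest
#' member molecule of any reference cluster; clusters are extended objects,
#' so proximity is measured to the cluster edge, not the centroid.
#'
#' @param targets a [localization_table()] (all rows used) or an n x 3
#'   coordinate matrix.
#' @param refs a `cluster_set` with at least one cluster.
#' @return numeric vector of distances (nm), one per target molecule.
#' @export
nearest_reference_distance <- function(targets, refs) {
  stopifnot(inherits(refs, "cluster_set"))
  pts <- if (inherits(targets, "localization_table")) loc_coords(targets) else as.matrix(targets)
  min_dist_to_set(pts, clustered_points(refs))
}

#' Percentage of target signal within a proximity shell
#'
#' @inheritParams nearest_reference_distance
#' @param shell_nm shell radius (nm), default 100.
#' @return percentage in `[0, 100]`; `NA` with a warning when there are no
#'   target molecules.
#' @export
fraction_within <- function(targets, refs, shell_nm = 100) {
  pts <- if (inherits(targets, "localization_table")) loc_coords(targets) else as.matrix(targets)
  if (nrow(pts) == 0L) {
    warning("no target molecules: fraction undefined")
    return(NA_real_)
  }
  d <- nearest_reference_distance(pts, refs)
  100 * mean(d <= shell_nm)
}

#' Density enrichment ratio within a proximity shell
#'
#' Ratio of target molecular density inside the shell (union of `shell_nm`
#' dilations of the reference clusters, clipped to the ID region) to the
#' density elsewhere in the ID region. The ID region is the 3D convex hull
#' of all supplied localizations; shell volume is estimated by seeded
#' Monte-Carlo integration over the hull.
#'
#' @inheritParams fraction_within
#' @param id_region a [localization_table()] (or n x 3 matrix) whose convex
#'   hull defines the ID region; typically the full multi-channel table.
#' @param mc_samples Monte-Carlo samples for the shell volume (>= 1e5 gives
#'   a relative SE below 1% for the defaults).
#' @param mc_seed fixed seed of the Monte-Carlo integration.
#' @return object of class `enrichment_ratio`: `ratio`, in/out densities
#'   (nm^-3), shell and complement volumes (nm^3), counts, and settings.
#'   `ratio` is `NA` (flagged, with a warning) when the outside density is
#'   zero or a volume vanishes.
#' @export
enrichment_ratio <- function(targets, refs, id_region, shell_nm = 100,
                             mc_samples = 1e5, mc_seed = 20231L) {
  tp <- if (inherits(targets, "localization_table")) loc_coords(targets) else as.matrix(targets)
  rp <- clustered_points(refs)
  idp <- if (inherits(id_region, "localization_table")) loc_coords(id_region) else as.matrix(id_region)
  hull <- convex_hull_3d(idp)
  if (hull$degenerate) stopf("ID region is degenerate: cannot form a 3D hull")
  # Monte-Carlo: uniform in the hull via rejection from its bounding box
  lo <- apply(idp, 2L, min); hi <- apply(idp, 2L, max)
  n_in_shell <- 0L; n_in_hull <- 0L
  with_local_seed(mc_seed, {
    remaining <- mc_samples
    while (n_in_hull < mc_samples && remaining < 50 * mc_samples) {
      m <- min(20000L, mc_samples)
      cand <- cbind(stats::runif(m, lo[1L], hi[1L]), stats::runif(m, lo[2L], hi[2L]),
                    stats::runif(m, lo[3L], hi[3L]))
      inside <- in_hull_3d(cand, hull)
      cand <- cand[inside, , drop = FALSE]
      take <- min(nrow(cand), mc_samples - n_in_hull)
      if (take > 0L) {
        cand <- cand[seq_len(take), , drop = FALSE]
        n_in_hull <- n_in_hull + take
        n_in_shell <- n_in_shell + sum(min_dist_to_set(cand, rp) <= shell_nm)
      }
      remaining <- remaining + m
    }
  })
  shell_frac <- n_in_shell / n_in_hull
  v_hull <- hull$volume
  v_shell <- shell_frac * v_hull
  v_out <- v_hull - v_shell
  d <- nearest_reference_distance(tp, refs)
  n_in <- sum(d <= shell_nm); n_out <- nrow(tp) - n_in
  dens_in <- if (v_shell > 0) n_in / v_shell else NA_real_
  dens_out <- if (v_out > 0) n_out / v_out else NA_real_
  ratio <- if (is.na(dens_in) || is.na(dens_out) || dens_out == 0) {
    warning("outside density is zero or a region volume vanishes: ratio undefined")
    NA_real_
  } else dens_in / dens_out
  structure(list(ratio = ratio, density_in = dens_in, density_out = dens_out,
                 shell_volume_nm3 = v_shell, complement_volume_nm3 = v_out,
                 hull_volume_nm3 = v_hull, n_in = n_in, n_out = n_out,
                 shell_nm = shell_nm, mc_samples = n_in_hull,
                 mc_seed = mc_seed),
            class = "enrichment_ratio")
}

#' @export
print.enrichment_ratio <- function(x, ...) {
  cat(sprintf("<enrichment_ratio> %.3g (in %.3g, out %.3g molecules/um^3; shell %g nm; %d/%d molecules)\n",
              x$ratio, x$density_in * 1e9, x$density_out * 1e9, x$shell_nm,
              x$n_in, x$n_out))
  invisible(x)
}

#' Full enrichment summary for a target channel
#'
#' Convenience wrapper computing, for one target channel, the percentage of
#' signal within `shell_nm` of GJ (Cx43) and MJ (N-cad) clusters and the
#' corresponding density enrichment ratios over the ID region.
#'
#' @param table multi-channel [localization_table()].
#' @param target_channel "NaV1.5" or "beta1".
#' @param gj_channel,mj_channel reference channel names.
#' @param shell_nm shell radius (nm).
#' @param eps_nm,min_pts clustering settings for the reference channels.
#' @param mc_samples,mc_seed Monte-Carlo settings, see [enrichment_ratio()].
#' @return object of class `enrichment_summary` with `pct_within_gj`,
#'   `pct_within_mj`, `enrichment_gj`, `enrichment_mj` and the underlying
#'   `enrichment_ratio` objects.
#' @export
id_enrichment_summary <- function(table, target_channel = "NaV1.5",
                                  gj_channel = "Cx43", mj_channel = "N-cad",
                                  shell_nm = 100, eps_nm = 50, min_pts = 5L,
                                  mc_samples = 1e5, mc_seed = 20231L) {
  targets <- table[table$channel == target_channel, , drop = FALSE]
  gj <- cluster_localizations(table, gj_channel, eps_nm, min_pts)
  mj <- cluster_localizations(table, mj_channel, eps_nm, min_pts)
  er_gj <- enrichment_ratio(targets, gj, table, shell_nm, mc_samples, mc_seed)
  er_mj <- enrichment_ratio(targets, mj, table, shell_nm, mc_samples, mc_seed)
  structure(list(target_channel = target_channel,
                 pct_within_gj = fraction_within(targets, gj, shell_nm),
                 pct_within_mj = fraction_within(targets, mj, shell_nm),
                 enrichment_gj = er_gj$ratio, enrichment_mj = er_mj$ratio,
                 detail = list(gj = er_gj, mj = er_mj),
                 shell_nm = shell_nm),
            class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf("<enrichment_summary> %s: %.1f%% within %g nm of GJ (enrichment %.2f); %.1f%% of MJ (enrichment %.2f)\n",
              x$target_channel, x$pct_within_gj, x$shell_nm, x$enrichment_gj,
              x$pct_within_mj, x$enrichment_mj))
  invisible(x)
}

#' Bivariate histogram of cluster value vs distance to reference
#'
#' Each target cluster contributes one count at (its centroid-to-nearest-
#' reference-edge distance, its value), where value is the cluster density,
#' count, or a supplied numeric vector (e.g. mass for volumetric objects).
#'
#' @param clusters a `cluster_set` of target clusters (or a list with
#'   `distance` and `value` vectors).
#' @param refs reference `cluster_set`.
#' @param distance_edges,value_edges bin edges (nm; value units).
#' @param value "density" or "count".
#' @return object of class `bivariate_histogram`: `counts` matrix
#'   (distance bins x value bins), the edges, and `n_contributing`.
#' @export
bivariate_histogram <- function(clusters, refs, distance_edges, value_edges,
                                value = c("density", "count")) {
  value <- match.arg(value)
  stopifnot(inherits(clusters, "cluster_set"))
  if (!length(clusters$clusters)) stopf("need >= 1 target cluster")
  cen <- do.call(rbind, lapply(clusters$clusters, function(c) c$centroid))
  d <- min_dist_to_set(cen, clustered_points(refs))
  v <- vapply(clusters$clusters, function(c)
    if (value == "density") c$density else as.numeric(c$count), numeric(1))
  bivariate_histogram_xy(d, v, distance_edges, value_edges)
}

# shared binning core (also used for volumetric mass histograms)
bivariate_histogram_xy <- function(d, v, distance_edges, value_edges) {
  ok <- is.finite(d) & is.finite(v) &
    d >= distance_edges[1L] & d <= distance_edges[length(distance_edges)] &
    v >= value_edges[1L] & v <= value_edges[length(value_edges)]
  di <- findInterval(d[ok], distance_edges, rightmost.closed = TRUE, all.inside = TRUE)
  vi <- findInterval(v[ok], value_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(distance_edges) - 1L, length(value_edges) - 1L)
  for (i in seq_along(di)) counts[di[i], vi[i]] <- counts[di[i], vi[i]] + 1L
  structure(list(counts = counts, distance_edges = distance_edges,
                 value_edges = value_edges, n_contributing = sum(ok),
                 n_dropped = sum(!ok)),
            class = "bivariate_histogram")
}

#' @export
print.bivariate_histogram <- function(x, ...) {
  cat(sprintf("<bivariate_histogram> %d x %d bins, %d clusters (%d out of range)\n",
              nrow(x$counts), ncol(x$counts), x$n_contributing, x$n_dropped))
  invisible(x)
}

#' @export
plot.bivariate_histogram <- function(x, ...) {
  graphics::image(x = x$distance_edges, y = x$value_edges, z = x$counts,
                  xlab = "distance to reference (nm)", ylab = "value",
                  main = "Bivariate histogram", useRaster = TRUE, ...)
  invisible(x)
}
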