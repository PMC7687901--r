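# Object-based segmentation in 3D (OBS3D): threshold at a fraction of the
# channel maximum, label 26-connected components, and quantify cluster mass
# (normalized intensity summed over the object) and its enrichment near a
# reference channel.

#' Segment 3D objects from one channel of a voxel image
#'
#' Intensities are normalized to the channel maximum; voxels at or above
#' `threshold_frac` are kept and grouped into 26-connected components;
#' components smaller than `min_voxels` are discarded (counted in
#' `n_discarded`).
#'
#' @param img a [voxel_image()].
#' @param channel channel name.
#' @param threshold_frac threshold as a fraction of the channel maximum,
#'   in (0, 1); default 0.5 (half-max).
#' @param min_voxels minimum object size in voxels (default 8).
#' @return object of class `object_set`: per object the voxel indices
#'   (linear), voxel count, volume (nm^3), mass (summed normalized
#'   intensity), and intensity-weighted centroid (nm); plus the threshold
#'   used and the image geometry.
#' @export
segment_objects_3d <- function(img, channel, threshold_frac = 0.5,
                               min_voxels = 8L) {
  stopifnot(inherits(img, "voxel_image"))
  if (!channel %in% names(img$channels)) stopf("channel '%s' not in image", channel)
  if (threshold_frac <= 0 || threshold_frac >= 1) stopf("`threshold_frac` must be in (0, 1)")
  arr <- img$channels[[channel]]
  mx <- max(arr)
  empty <- structure(list(channel = channel, objects = list(),
                          threshold_frac = threshold_frac,
                          min_voxels = as.integer(min_voxels),
                          n_discarded = 0L, dims = dim(arr),
                          voxel_nm = img$voxel_nm),
                     class = "object_set")
  if (mx <= 0) return(empty)
  norm <- arr / mx
  fg <- which(norm >= threshold_frac)
  if (!length(fg)) return(empty)
  labels <- label_components_26(dim(arr), fg)
  vox_vol <- prod(img$voxel_nm)
  objs <- lapply(split(fg, labels), function(idx) {
    w <- norm[idx]
    co <- arrayInd(idx, dim(arr))
    cen <- colSums(co * w) / sum(w)
    list(voxels = idx, n_voxels = length(idx),
         volume_nm3 = length(idx) * vox_vol,
         mass = sum(w),
         centroid_nm = (cen - 0.5) * img$voxel_nm)
  })
  small <- vapply(objs, function(o) o$n_voxels < min_voxels, logical(1))
  structure(list(channel = channel, objects = unname(objs[!small]),
                 threshold_frac = threshold_frac,
                 min_voxels = as.integer(min_voxels),
                 n_discarded = sum(small), dims = dim(arr),
                 voxel_nm = img$voxel_nm),
            class = "object_set")
}

# 26-connected component labels of foreground voxels `fg` (linear indices)
# in an array of dimension `dims`. Adjacent foreground voxels are connected
# via edges over the 13 half-neighbourhood offsets; components come from
# igraph. Returns an integer label per element of fg.
label_components_26 <- function(dims, fg) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  co <- arrayInd(fg, dims)
  idx_map <- integer(prod(dims))
  idx_map[fg] <- seq_along(fg)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1L] != 0 | offs[, 2L] != 0 | offs[, 3L] != 0, ]
  offs <- offs[1:(nrow(offs) / 2), , drop = FALSE]  # half neighbourhood
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    xx <- co[, 1L] + offs[k, 1L]; yy <- co[, 2L] + offs[k, 2L]; zz <- co[, 3L] + offs[k, 3L]
    ok <- xx >= 1L & xx <= nx & yy >= 1L & yy <= ny & zz >= 1L & zz <= nz
    if (!any(ok)) next
    nb_lin <- (zz[ok] - 1L) * nx * ny + (yy[ok] - 1L) * nx + xx[ok]
    nb_pos <- idx_map[nb_lin]
    hit <- nb_pos > 0L
    if (any(hit))
      edges <- c(edges, rbind(which(ok)[hit], nb_pos[hit]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> channel %s: %d objects (>= %d voxels; %d discarded) at threshold %.2f of max\n",
              x$channel, length(x$objects), x$min_voxels, x$n_discarded,
              x$threshold_frac))
  invisible(x)
}

#' Cluster mass of a segmented object
#'
#' Mass is the normalized intensity summed over the object's voxels; it is
#' invariant to global intensity scaling and equals the object volume (in
#' voxels) times its mean normalized intensity.
#'
#' @param obj one element of an `object_set`'s `objects` list.
#' @return numeric mass.
#' @export
cluster_mass <- function(obj) {
  if (is.null(obj$mass)) stopf("not a segmented object")
  obj$mass
}

# distance (nm) from each target object centroid to the nearest reference
# object surface (nearest member voxel centre), on physical coordinates
object_centroid_ref_distance <- function(targets, refs) {
  if (!length(refs$objects)) stopf("no reference objects")
  rp <- do.call(rbind, lapply(refs$objects, function(o)
    sweep(arrayInd(o$voxels, refs$dims) - 0.5, 2L, refs$voxel_nm, "*")))
  cen <- do.call(rbind, lapply(targets$objects, function(o) o$centroid_nm))
  min_dist_to_set(cen, rp)
}

#' Mass enrichment ratio near a reference channel
#'
#' A target object is "near" when its centroid lies within `shell_nm` of the
#' nearest reference-object voxel; the ratio is total near mass over total
#' far mass. Whole objects are assigned to one side.
#'
#' @param targets,refs `object_set`s (e.g. NaV1.5 vs Cx43).
#' @param shell_nm proximity threshold (nm), default 100.
#' @return object of class `mass_enrichment`: `ratio` (`NA`, flagged with a
#'   warning, when the far mass is zero), near/far masses and counts.
#' @export
mass_enrichment_ratio <- function(targets, refs, shell_nm = 100) {
  stopifnot(inherits(targets, "object_set"), inherits(refs, "object_set"))
  if (!length(targets$objects)) stopf("no target objects")
  d <- object_centroid_ref_distance(targets, refs)
  mass <- vapply(targets$objects, cluster_mass, numeric(1))
  near <- d < shell_nm
  m_near <- sum(mass[near]); m_far <- sum(mass[!near])
  ratio <- if (m_far <= 0) {
    warning("no far mass: mass enrichment ratio undefined")
    NA_real_
  } else m_near / m_far
  structure(list(ratio = ratio, mass_near = m_near, mass_far = m_far,
                 n_near = sum(near), n_far = sum(!near),
                 shell_nm = shell_nm),
            class = "mass_enrichment")
}

#' @export
print.mass_enrichment <- function(x, ...) {
  cat(sprintf("<mass_enrichment> near/far mass ratio %.3g (%d near, %d far objects; shell %g nm)\n",
              x$ratio, x$n_near, x$n_far, x$shell_nm))
  invisible(x)
}

#' Bivariate histogram of object mass vs distance to reference
#'
#' @param targets,refs `object_set`s.
#' @param distance_edges,mass_edges bin edges.
#' @return a `bivariate_histogram` (see [bivariate_histogram()]).
#' @export
mass_distance_histogram <- function(targets, refs, distance_edges, mass_edges) {
  stopifnot(inherits(targets, "object_set"))
  if (!length(targets$objects)) stopf("need >= 1 target object")
  d <- object_centroid_ref_distance(targets, refs)
  m <- vapply(targets$objects, cluster_mass, numeric(1))
  bivariate_histogram_xy(d, m, distance_edges, mass_edges)
}
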