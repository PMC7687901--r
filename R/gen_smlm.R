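# Synthetic intercalated-disk localization scenes: Cx43 (GJ) and N-cadherin
# (MJ) reference clusters on disjoint halves of the field plus a target
# channel (NaV1.5 or beta1) with controlled fractions of its signal within
# the 100 nm proximity shells, and a PSF-blurred voxel rendering bridging the
# point clouds to the volumetric (OBS3D) stage.

#' Construct a localization table
#'
#' @param x_nm,y_nm,z_nm coordinates (nm).
#' @param channel character channel labels; the declared set is NaV1.5,
#'   beta1, Cx43, N-cad.
#' @param precision_xy_nm,precision_z_nm localization precision per molecule.
#' @return data frame of class `localization_table`.
#' @export
localization_table <- function(x_nm, y_nm, z_nm, channel,
                               precision_xy_nm = 20, precision_z_nm = 50) {
  if (length(x_nm) && !all(is.finite(c(x_nm, y_nm, z_nm))))
    stopf("coordinates must be finite")
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   z_nm = as.numeric(z_nm), channel = as.character(channel),
                   precision_xy_nm = rep_len(precision_xy_nm, length(x_nm)),
                   precision_z_nm = rep_len(precision_z_nm, length(x_nm)),
                   stringsAsFactors = FALSE)
  class(df) <- c("localization_table", "data.frame")
  df
}

loc_coords <- function(table, channel = NULL) {
  if (!is.null(channel)) table <- table[table$channel == channel, , drop = FALSE]
  as.matrix(table[, c("x_nm", "y_nm", "z_nm")])
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table> %d localizations; channels: %s\n",
              nrow(x), paste(sprintf("%s (%d)", names(table(x$channel)),
                                     as.integer(table(x$channel))),
                             collapse = ", ")))
  invisible(x)
}

# uniform points inside a sphere of radius r around 0
runif_sphere <- function(n, r) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  u * r * stats::runif(n)^(1 / 3)
}

#' Generate a synthetic ID point cloud
#'
#' Reference clusters are compact blobs jittered by the localization
#' precision; GJ clusters occupy the left half of the field and MJ clusters
#' the right half, so proximity labels are unambiguous. Target molecules are
#' drawn from a three-component mixture (within `shell_nm` of a GJ cluster,
#' within `shell_nm` of an MJ cluster, elsewhere) with the preset fractions.
#' Jitter is applied during placement with a rejection step, so the fractions
#' hold exactly (up to multinomial sampling) in the emitted table: the
#' per-molecule labels in the ground truth are the geometric truth of the
#' observed coordinates.
#'
#' When `density_ratio_gj` is supplied instead of fractions, the mixture
#' weights are derived from Monte-Carlo shell-volume fractions so the cloud
#' realizes the requested in-shell/out-of-shell density ratios.
#'
#' @param preset an [id_cloud_preset()].
#' @param seed integer seed (bit-determinism contract).
#' @return list with `table` (a [localization_table()] with Cx43, N-cad and
#'   target channels) and `truth` (class `ground_truth`: per-molecule
#'   component labels, realized fractions, shell volume fractions, realized
#'   density ratios, seed, preset).
#' @export
gen_id_point_cloud <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "id_cloud_preset"))
  fx <- preset$field_nm[1L]; fy <- preset$field_nm[2L]; fz <- preset$field_nm[3L]
  r <- preset$ref_cluster_radius_nm
  shell <- preset$shell_nm
  sxy <- preset$loc_precision_xy_nm; sz <- preset$loc_precision_z_nm
  gap <- r + shell + 50   # clearance of cluster centres from the half line

  with_local_seed(seed, {
    # localizations are confined to the ID volume (the field box): jitter
    # that would carry a molecule outside is redrawn, truncating the
    # localization-error distribution at the field boundary
    jitter_in_box <- function(base) {
      out <- matrix(NA_real_, nrow(base), 3L)
      todo <- seq_len(nrow(base))
      for (it in 1:500) {
        if (!length(todo)) break
        k <- length(todo)
        cand <- base[todo, , drop = FALSE] +
          cbind(stats::rnorm(k, 0, sxy), stats::rnorm(k, 0, sxy), stats::rnorm(k, 0, sz))
        ok <- cand[, 1L] >= 0 & cand[, 1L] <= fx & cand[, 2L] >= 0 &
              cand[, 2L] <= fy & cand[, 3L] >= 0 & cand[, 3L] <= fz
        out[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
      if (any(is.na(out[, 1L]))) stopf("jitter rejection failed: blob extends far outside the field")
      out
    }
    place_refs <- function(k, x_lo, x_hi) {
      if (k == 0L) return(matrix(numeric(0), 0L, 3L))
      cen <- cbind(stats::runif(k, x_lo + r, x_hi - r),
                   stats::runif(k, r, fy - r),
                   stats::runif(k, min(r, fz / 2), max(fz - r, fz / 2)))
      m <- preset$ref_molecules_per_cluster
      pts <- do.call(rbind, lapply(seq_len(k), function(i)
        sweep(runif_sphere(m, r), 2L, cen[i, ], "+")))
      pts[, 1L] <- pmin(pmax(pts[, 1L], 0), fx)
      pts[, 2L] <- pmin(pmax(pts[, 2L], 0), fy)
      pts[, 3L] <- pmin(pmax(pts[, 3L], 0), fz)
      jitter_in_box(pts)
    }
    gj <- place_refs(preset$n_ref_gj, 0, fx / 2 - gap)
    mj <- place_refs(preset$n_ref_mj, fx / 2 + gap, fx)

    # Monte-Carlo shell volume fractions of the field box; needed to derive
    # mixture weights from density ratios and for the realized density-ratio
    # ground truth (skipped for plain-fraction presets, where the fraction
    # itself is the truth)
    if (!is.null(preset$density_ratio_gj) || preset$uniform_targets) {
      n_mc <- 20000L
      mc <- cbind(stats::runif(n_mc, 0, fx), stats::runif(n_mc, 0, fy),
                  stats::runif(n_mc, 0, fz))
      near_gj_mc <- if (nrow(gj)) min_dist_to_set(mc, gj) <= shell else rep(FALSE, n_mc)
      near_mj_mc <- if (nrow(mj)) min_dist_to_set(mc, mj) <= shell else rep(FALSE, n_mc)
      v <- c(gj = mean(near_gj_mc), mj = mean(near_mj_mc),
             rest = mean(!near_gj_mc & !near_mj_mc))
    } else {
      v <- c(gj = NA_real_, mj = NA_real_, rest = NA_real_)
    }

    if (!is.null(preset$density_ratio_gj)) {
      rho_gj <- preset$density_ratio_gj
      rho_mj <- preset$density_ratio_mj %||% 1
      w <- c(rho_gj * v[["gj"]], rho_mj * v[["mj"]], v[["rest"]])
      fracs <- w / sum(w)
    } else {
      fracs <- c(preset$frac_near_gj, preset$frac_near_mj,
                 1 - preset$frac_near_gj - preset$frac_near_mj)
    }

    n <- preset$n_target_molecules
    if (preset$uniform_targets) {
      tp <- cbind(stats::runif(n, 0, fx), stats::runif(n, 0, fy),
                  stats::runif(n, 0, fz))
      lab <- rep(3L, n)
      if (nrow(gj)) lab[min_dist_to_set(tp, gj) <= shell] <- 1L
      if (nrow(mj)) lab[min_dist_to_set(tp, mj) <= shell] <- 2L
    } else {
      cnt <- as.integer(stats::rmultinom(1L, n, fracs))
      if (cnt[1L] > 0L && !nrow(gj)) stopf("frac_near_gj > 0 but no GJ clusters")
      if (cnt[2L] > 0L && !nrow(mj)) stopf("frac_near_mj > 0 but no MJ clusters")
      place_near <- function(m, refs) {
        out <- matrix(NA_real_, m, 3L)
        todo <- seq_len(m)
        for (it in 1:200) {
          if (!length(todo)) break
          k <- length(todo)
          anchor <- refs[sample.int(nrow(refs), k, replace = TRUE), , drop = FALSE]
          cand <- anchor + runif_sphere(k, shell) +
            cbind(stats::rnorm(k, 0, sxy), stats::rnorm(k, 0, sxy), stats::rnorm(k, 0, sz))
          ok <- min_dist_to_set(cand, refs) <= shell &
            cand[, 1L] >= 0 & cand[, 1L] <= fx & cand[, 2L] >= 0 &
            cand[, 2L] <= fy & cand[, 3L] >= 0 & cand[, 3L] <= fz
          out[todo[ok], ] <- cand[ok, , drop = FALSE]
          todo <- todo[!ok]
        }
        if (length(todo)) stopf("could not place near-shell molecules (field too tight)")
        out
      }
      place_far <- function(m) {
        out <- matrix(NA_real_, m, 3L)
        todo <- seq_len(m)
        for (it in 1:200) {
          if (!length(todo)) break
          k <- length(todo)
          cand <- cbind(stats::runif(k, 0, fx), stats::runif(k, 0, fy),
                        stats::runif(k, 0, fz)) +
            cbind(stats::rnorm(k, 0, sxy), stats::rnorm(k, 0, sxy), stats::rnorm(k, 0, sz))
          ok <- cand[, 1L] >= 0 & cand[, 1L] <= fx & cand[, 2L] >= 0 &
            cand[, 2L] <= fy & cand[, 3L] >= 0 & cand[, 3L] <= fz
          if (nrow(gj)) ok <- ok & min_dist_to_set(cand, gj) > shell
          if (nrow(mj)) ok <- ok & min_dist_to_set(cand, mj) > shell
          out[todo[ok], ] <- cand[ok, , drop = FALSE]
          todo <- todo[!ok]
        }
        if (length(todo)) stopf("could not place far molecules (shells fill the field)")
        out
      }
      tp <- rbind(if (cnt[1L]) place_near(cnt[1L], gj),
                  if (cnt[2L]) place_near(cnt[2L], mj),
                  if (cnt[3L]) place_far(cnt[3L]))
      if (is.null(tp)) tp <- matrix(numeric(0), 0L, 3L)
      lab <- rep.int(1:3, cnt)
    }

    tab <- localization_table(
      c(gj[, 1L], mj[, 1L], tp[, 1L]),
      c(gj[, 2L], mj[, 2L], tp[, 2L]),
      c(gj[, 3L], mj[, 3L], tp[, 3L]),
      c(rep("Cx43", nrow(gj)), rep("N-cad", nrow(mj)),
        rep(preset$target_channel, nrow(tp))),
      precision_xy_nm = sxy, precision_z_nm = sz)

    n1 <- sum(lab == 1L); n2 <- sum(lab == 2L); n3 <- sum(lab == 3L)
    vb <- prod(preset$field_nm)
    dens <- function(k, vf) if (vf > 0 && n > 0) (k / (vf * vb)) else NA_real_
    rho_real_gj <- if (isTRUE(v[["gj"]] > 0) && n3 > 0) dens(n1, v[["gj"]]) / dens(n3, v[["rest"]]) else NA_real_
    rho_real_mj <- if (isTRUE(v[["mj"]] > 0) && n3 > 0) dens(n2, v[["mj"]]) / dens(n3, v[["rest"]]) else NA_real_

    truth <- structure(list(
      module = "id_point_cloud", preset = preset, seed = as.integer(seed),
      labels = lab,
      frac_near_gj = if (n > 0) n1 / n else NA_real_,
      frac_near_mj = if (n > 0) n2 / n else NA_real_,
      shell_volume_fractions = v,
      density_ratio_gj = rho_real_gj,
      density_ratio_mj = rho_real_mj), class = "ground_truth")
    list(table = tab, truth = truth)
  })
}

#' Construct a voxel image
#'
#' @param channels named list of 3D arrays (dim nx, ny, nz), non-negative.
#' @param voxel_nm numeric c(x, y, z) voxel size (nm).
#' @return object of class `voxel_image`.
#' @export
voxel_image <- function(channels, voxel_nm) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stopf("`channels` must be a named list")
  voxel_nm <- as.numeric(voxel_nm)
  if (length(voxel_nm) != 3L || any(voxel_nm <= 0)) stopf("`voxel_nm` must be 3 positive sizes")
  d <- dim(channels[[1L]])
  for (ch in channels) {
    if (!identical(dim(ch), d)) stopf("all channels must share dimensions")
    if (any(ch < 0)) stopf("intensities must be non-negative")
  }
  structure(list(channels = channels, voxel_nm = voxel_nm),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<voxel_image> %d x %d x %d voxels (%g x %g x %g nm), channels: %s\n",
              d[1L], d[2L], d[3L], x$voxel_nm[1L], x$voxel_nm[2L], x$voxel_nm[3L],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Render a localization table as a PSF-blurred voxel image
#'
#' Each molecule contributes a separable anisotropic Gaussian kernel
#' (integrated over voxel extents, so every interior molecule deposits unit
#' total intensity). Emulates a deconvolved volumetric stack of the same
#' scene. Molecules outside the field are dropped with a message.
#'
#' @param table a [localization_table()].
#' @param psf_sigma_nm per-axis Gaussian sigma c(x, y, z) in nm.
#' @param voxel_nm per-axis voxel size (nm), each >= 1.
#' @param field_nm field extent c(x, y, z); default spans the table plus
#'   4 sigma padding.
#' @param origin_nm lower corner of the field; default c(0, 0, 0) clamped to
#'   the padded table extent.
#' @param channels channels to render; default all present in the table (an
#'   empty table renders a single all-zero channel named "signal").
#' @return a [voxel_image()] with one channel per channel present in the
#'   table; attribute `n_dropped` counts out-of-field molecules.
#' @export
render_voxel_image <- function(table, psf_sigma_nm = c(40, 40, 60),
                               voxel_nm = c(25, 25, 50), field_nm = NULL,
                               origin_nm = NULL, channels = NULL) {
  stopifnot(inherits(table, "localization_table"))
  voxel_nm <- as.numeric(voxel_nm)
  if (any(voxel_nm < 1)) stopf("voxel size must be >= 1 nm per axis")
  psf_sigma_nm <- pmax(as.numeric(psf_sigma_nm), 1e-6)
  pad <- 4 * psf_sigma_nm
  xyz <- loc_coords(table)
  if (is.null(origin_nm))
    origin_nm <- if (nrow(xyz)) pmin(apply(xyz, 2L, min) - pad, 0) else c(0, 0, 0)
  if (is.null(field_nm))
    field_nm <- if (nrow(xyz)) apply(xyz, 2L, max) + pad - origin_nm else voxel_nm * 8
  dims <- pmax(as.integer(ceiling(field_nm / voxel_nm)), 2L)

  chans <- channels %||% unique(table$channel)
  if (!length(chans)) chans <- "signal"   # empty table -> one all-zero channel
  out <- lapply(chans, function(ch) {
    arr <- array(0, dims)
    p <- loc_coords(table, ch)
    if (!nrow(p)) return(arr)
    rel <- sweep(p, 2L, origin_nm)
    inside <- rel[, 1L] >= 0 & rel[, 1L] <= field_nm[1L] &
              rel[, 2L] >= 0 & rel[, 2L] <= field_nm[2L] &
              rel[, 3L] >= 0 & rel[, 3L] <= field_nm[3L]
    n_drop <- sum(!inside)
    if (n_drop) message(sprintf("render_voxel_image: dropped %d molecule(s) outside the field (channel %s)", n_drop, ch))
    rel <- rel[inside, , drop = FALSE]
    for (i in seq_len(nrow(rel))) {
      w <- vector("list", 3L)
      rng <- vector("list", 3L)
      for (ax in 1:3) {
        lo <- max(1L, floor((rel[i, ax] - 4 * psf_sigma_nm[ax]) / voxel_nm[ax]) + 1L)
        hi <- min(dims[ax], ceiling((rel[i, ax] + 4 * psf_sigma_nm[ax]) / voxel_nm[ax]))
        edges <- (seq(lo - 1L, hi)) * voxel_nm[ax]
        cdf <- stats::pnorm(edges, rel[i, ax], psf_sigma_nm[ax])
        w[[ax]] <- diff(cdf)
        rng[[ax]] <- lo:hi
      }
      arr[rng[[1L]], rng[[2L]], rng[[3L]]] <-
        arr[rng[[1L]], rng[[2L]], rng[[3L]]] +
        outer(outer(w[[1L]], w[[2L]]), w[[3L]])
    }
    attr(arr, "n_dropped") <- n_drop
    arr
  })
  names(out) <- chans
  n_dropped <- sum(vapply(out, function(a) attr(a, "n_dropped") %||% 0L, numeric(1)))
  out <- lapply(out, function(a) { attr(a, "n_dropped") <- NULL; a })
  img <- voxel_image(out, voxel_nm)
  attr(img, "origin_nm") <- origin_nm
  attr(img, "n_dropped") <- as.integer(n_dropped)
  img
}
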