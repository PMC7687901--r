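# Computational geometry primitives: 3D convex hull (quickhull), hull volume,
# point-in-hull tests, and 2D polyline utilities. Self-contained because the
# package needs hull volumes for localization clusters, a reproducible
# ID-region definition, and Monte-Carlo shell volumes.

#' Convex hull of a 3D point set
#'
#' Quickhull. Returns the hull facets (vertex index triples with outward unit
#' normals), the hull vertices, and the enclosed volume. Degenerate inputs
#' (fewer than 4 points, or points of affine rank < 3) yield `volume = 0` and
#' no facets.
#'
#' @param pts numeric matrix, n x 3, one point per row (nm or any length unit).
#' @return list with `faces` (m x 3 integer matrix of point-row indices),
#'   `normals` (m x 3 outward unit normals), `offsets` (m, facet plane offsets
#'   so that interior points satisfy `normal . x <= offset`), `vertices`
#'   (indices of points on the hull), `volume` (cubic units), and
#'   `degenerate` flag.
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stopf("`pts` must have 3 columns")
  n <- nrow(pts)
  degen <- list(faces = NULL, normals = NULL, offsets = NULL,
                vertices = integer(0), volume = 0, degenerate = TRUE)
  if (n < 4L) return(degen)
  scale <- max(apply(pts, 2L, function(v) diff(range(v))), 1e-12)
  tol <- 1e-9 * scale

  # initial simplex: extremes along x, furthest from that line, then plane
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (i1 == i2) { i2 <- which.max(rowSums(sweep(pts, 2L, pts[i1, ])^2)) }
  d12 <- pts[i2, ] - pts[i1, ]
  if (sqrt(sum(d12^2)) < tol) return(degen)
  rel <- sweep(pts, 2L, pts[i1, ])
  cr <- cbind(rel[, 2L] * d12[3L] - rel[, 3L] * d12[2L],
              rel[, 3L] * d12[1L] - rel[, 1L] * d12[3L],
              rel[, 1L] * d12[2L] - rel[, 2L] * d12[1L])
  linedist <- sqrt(rowSums(cr^2)) / sqrt(sum(d12^2))
  i3 <- which.max(linedist)
  if (linedist[i3] < tol) return(degen)
  nrm0 <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  planedist <- abs(rel %*% nrm0) / sqrt(sum(nrm0^2))
  i4 <- which.max(planedist)
  if (planedist[i4] < tol) return(degen)

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  mk_face <- function(a, b, c) {
    nrm <- cross3(pts[b, ] - pts[a, ], pts[c, ] - pts[a, ])
    len <- sqrt(sum(nrm^2))
    nrm <- nrm / len
    off <- sum(nrm * pts[a, ])
    if (sum(nrm * interior) > off) { tmp <- b; b <- c; c <- tmp; nrm <- -nrm; off <- -off }
    list(v = c(a, b, c), n = nrm, d = off, alive = TRUE, outside = integer(0))
  }
  faces <- list(mk_face(i1, i2, i3), mk_face(i1, i2, i4),
                mk_face(i1, i3, i4), mk_face(i2, i3, i4))

  # assign each point to the first face it lies strictly above
  unassigned <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (f in seq_along(faces)) {
    if (!length(unassigned)) break
    above <- (pts[unassigned, , drop = FALSE] %*% faces[[f]]$n)[, 1L] - faces[[f]]$d > tol
    faces[[f]]$outside <- unassigned[above]
    unassigned <- unassigned[!above]
  }

  repeat {
    fi <- 0L
    for (f in seq_along(faces)) {
      if (faces[[f]]$alive && length(faces[[f]]$outside)) { fi <- f; break }
    }
    if (fi == 0L) break
    fc <- faces[[fi]]
    h <- (pts[fc$outside, , drop = FALSE] %*% fc$n)[, 1L] - fc$d
    p <- fc$outside[which.max(h)]
    # visible faces
    vis <- integer(0)
    for (f in seq_along(faces)) {
      if (faces[[f]]$alive &&
          sum(faces[[f]]$n * pts[p, ]) - faces[[f]]$d > tol) vis <- c(vis, f)
    }
    # horizon: edges appearing in exactly one visible face
    edges <- do.call(rbind, lapply(vis, function(f) {
      v <- faces[[f]]$v
      rbind(sort(c(v[1L], v[2L])), sort(c(v[2L], v[3L])), sort(c(v[1L], v[3L])))
    }))
    key <- paste(edges[, 1L], edges[, 2L])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    pool <- unique(unlist(lapply(vis, function(f) faces[[f]]$outside)))
    pool <- setdiff(pool, p)
    for (f in vis) faces[[f]]$alive <- FALSE
    for (e in seq_len(nrow(horizon))) {
      nf <- mk_face(horizon[e, 1L], horizon[e, 2L], p)
      if (length(pool)) {
        above <- (pts[pool, , drop = FALSE] %*% nf$n)[, 1L] - nf$d > tol
        nf$outside <- pool[above]
        pool <- pool[!above]
      }
      faces[[length(faces) + 1L]] <- nf
    }
    if (length(faces) > 60L && sum(vapply(faces, function(f) !f$alive, logical(1))) > 30L)
      faces <- Filter(function(f) f$alive, faces)
  }
  faces <- Filter(function(f) f$alive, faces)
  fv <- do.call(rbind, lapply(faces, function(f) f$v))
  normals <- do.call(rbind, lapply(faces, function(f) f$n))
  offsets <- vapply(faces, function(f) f$d, numeric(1))
  vol <- sum(vapply(faces, function(f) {
    a <- pts[f$v[1L], ] - interior; b <- pts[f$v[2L], ] - interior
    c3 <- pts[f$v[3L], ] - interior
    abs(sum(a * cross3(b, c3))) / 6
  }, numeric(1)))
  list(faces = fv, normals = normals, offsets = offsets,
       vertices = sort(unique(as.integer(fv))), volume = vol, degenerate = FALSE)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Test points against a convex hull
#'
#' @param pts n x 3 matrix of query points.
#' @param hull result of [convex_hull_3d()].
#' @param tol slack (same units as coordinates) on the facet inequalities.
#' @return logical vector, `TRUE` where the point lies inside (or on) the hull.
#' @export
in_hull_3d <- function(pts, hull, tol = 1e-7) {
  if (isTRUE(hull$degenerate)) stopf("hull is degenerate; no interior defined")
  pts <- as.matrix(pts)
  res <- rep(TRUE, nrow(pts))
  # blockwise to bound the n x m facet matrix
  i <- 1L
  while (i <= nrow(pts)) {
    j <- min(i + 4095L, nrow(pts))
    s <- pts[i:j, , drop = FALSE] %*% t(hull$normals)
    res[i:j] <- rowSums(sweep(s, 2L, hull$offsets + tol) > 0) == 0L
    i <- j + 1L
  }
  res
}

# Volume of the convex hull of a point cloud; 0 for degenerate clouds.
hull_volume <- function(pts) {
  if (nrow(pts) < 4L) return(0)
  h <- convex_hull_3d(pts)
  if (h$degenerate) 0 else h$volume
}

# ---- 2D polyline utilities (ultrastructure module) ----

# Minimum distance from each point in p (n x 2) to polyline vl (m x 2).
points_to_polyline_dist <- function(p, vl) {
  p <- as.matrix(p); vl <- as.matrix(vl)
  m <- nrow(vl)
  if (m < 2L) stopf("polyline needs >= 2 vertices")
  best <- rep(Inf, nrow(p))
  for (s in seq_len(m - 1L)) {
    a <- vl[s, ]; b <- vl[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- sqrt((p[, 1L] - a[1L])^2 + (p[, 2L] - a[2L])^2)
    } else {
      t <- ((p[, 1L] - a[1L]) * ab[1L] + (p[, 2L] - a[2L]) * ab[2L]) / len2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((a[1L] + t * ab[1L] - p[, 1L])^2 + (a[2L] + t * ab[2L] - p[, 2L])^2)
    }
    best <- pmin(best, d)
  }
  best
}

# Resample a polyline at n points equally spaced by arclength (includes ends).
resample_polyline <- function(vl, n) {
  vl <- as.matrix(vl)
  seg <- sqrt(rowSums(diff(vl)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stopf("polyline has zero length")
  s <- seq(0, total, length.out = n)
  x <- stats::approx(cum, vl[, 1L], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, vl[, 2L], xout = s, ties = "ordered")$y
  list(points = cbind(x, y), arclength = s)
}

# Do two polylines cross? Returns NULL or the approximate crossing location.
polyline_crossing <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  for (i in seq_len(nrow(a) - 1L)) {
    p <- a[i, ]; r <- a[i + 1L, ] - p
    q0 <- b[-nrow(b), , drop = FALSE]
    s <- b[-1L, , drop = FALSE] - q0
    denom <- r[1L] * s[, 2L] - r[2L] * s[, 1L]
    dq <- cbind(q0[, 1L] - p[1L], q0[, 2L] - p[2L])
    t <- (dq[, 1L] * s[, 2L] - dq[, 2L] * s[, 1L]) / denom
    u <- (dq[, 1L] * r[2L] - dq[, 2L] * r[1L]) / denom
    hit <- is.finite(t) & is.finite(u) & t > 0 & t < 1 & u > 0 & u < 1
    if (any(hit)) {
      j <- which(hit)[1L]
      return(c(x = p[1L] + t[j] * r[1L], y = p[2L] + t[j] * r[2L]))
    }
  }
  NULL
}
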