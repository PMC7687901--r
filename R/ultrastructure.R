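# TEM-stage quantification: intermembrane distance profiles from digitized
# membrane trace pairs, plus the paired-trace generator with an analytic
# sinusoidal gap profile.

#' Construct a membrane trace pair
#'
#' @param trace_a,trace_b ordered polylines, n x 2 matrices in nm. Distances
#'   are measured from `trace_a` to `trace_b` by convention.
#' @param site site label, "GJ-adjacent" or "MJ-adjacent".
#' @return object of class `membrane_pair`.
#' @export
membrane_pair <- function(trace_a, trace_b, site = c("GJ-adjacent", "MJ-adjacent")) {
  site <- match.arg(site)
  trace_a <- as.matrix(trace_a); trace_b <- as.matrix(trace_b)
  if (nrow(trace_a) < 2L || nrow(trace_b) < 2L)
    stopf("each trace needs >= 2 vertices")
  if (ncol(trace_a) != 2L || ncol(trace_b) != 2L) stopf("traces must be 2D (nm)")
  structure(list(trace_a = trace_a, trace_b = trace_b, site = site),
            class = "membrane_pair")
}

#' @export
print.membrane_pair <- function(x, ...) {
  cat(sprintf("<membrane_pair> %s: %d + %d vertices\n", x$site,
              nrow(x$trace_a), nrow(x$trace_b)))
  invisible(x)
}

#' Generate a synthetic membrane trace pair
#'
#' Trace A runs straight over `length_nm`; trace B is offset perpendicular
#' to it so the gap at arclength s equals
#' `mean_gap_nm + gap_waviness_nm * sin(2*pi*s/length_nm)`. The whole pair
#' can be rigidly rotated. The ground truth carries the analytic profile.
#'
#' @param preset a [membrane_preset()].
#' @param seed integer seed; kept for interface uniformity and recorded in
#'   the ground truth (the default pair is deterministic).
#' @return list with `pair` (a [membrane_pair()]) and `truth` (class
#'   `ground_truth` with the analytic gap profile).
#' @export
gen_membrane_pair <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "membrane_preset"))
  n <- preset$n_vertices
  s <- seq(0, preset$length_nm, length.out = n)
  gap <- preset$mean_gap_nm +
    preset$gap_waviness_nm * sin(2 * pi * s / preset$length_nm)
  a <- cbind(s, rep(0, n))
  b <- cbind(s, gap)
  th <- preset$angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  a <- a %*% t(rot); b <- b %*% t(rot)
  truth <- structure(list(module = "membrane_pair", preset = preset,
                          seed = as.integer(seed),
                          arclength_nm = s, gap_nm = gap,
                          mean_gap_nm = preset$mean_gap_nm),
                     class = "ground_truth")
  list(pair = membrane_pair(a, b, preset$site), truth = truth)
}

#' Intermembrane distance profile
#'
#' Samples `n_samples` points equally spaced by arclength along trace A and
#' measures, at each, the minimum Euclidean distance to trace B
#' (point-to-segment). Crossing traces are rejected with the crossing
#' location.
#'
#' @param pair a [membrane_pair()].
#' @param n_samples number of sample points (>= 10; default 120, which
#'   exceeds 100 measurements per micrograph).
#' @return object of class `distance_profile`: `arclength_nm`,
#'   `distance_nm`, `mean_nm`, `se_nm`, `n`, `site`.
#' @export
intermembrane_distance <- function(pair, n_samples = 120L) {
  stopifnot(inherits(pair, "membrane_pair"))
  if (n_samples < 10L) stopf("`n_samples` must be >= 10")
  cross <- polyline_crossing(pair$trace_a, pair$trace_b)
  if (!is.null(cross))
    stopf("traces cross near (%.1f, %.1f) nm: not a valid membrane pair",
          cross[1L], cross[2L])
  rs <- resample_polyline(pair$trace_a, n_samples)
  d <- points_to_polyline_dist(rs$points, pair$trace_b)
  structure(list(arclength_nm = rs$arclength, distance_nm = d,
                 mean_nm = mean(d), se_nm = stats::sd(d) / sqrt(length(d)),
                 n = length(d), site = pair$site),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %s: %.2f +/- %.2f nm (mean +/- SE, n = %d)\n",
              x$site, x$mean_nm, x$se_nm, x$n))
  invisible(x)
}

#' @export
plot.distance_profile <- function(x, ...) {
  graphics::plot(x$arclength_nm, x$distance_nm, type = "l",
                 xlab = "arclength (nm)", ylab = "intermembrane distance (nm)",
                 main = x$site, ...)
  graphics::abline(h = x$mean_nm, lty = 2)
  invisible(x)
}

#' Pool distance profiles of one site
#'
#' Concatenates the samples of all profiles sharing a site label and reports
#' the pooled mean and SE (identical to computing them on the concatenated
#' samples).
#'
#' @param profiles list of `distance_profile`s.
#' @param site site label all profiles must share.
#' @return object of class `distance_profile` over the pooled samples.
#' @export
pool_site_distances <- function(profiles, site) {
  if (!length(profiles)) stopf("need >= 1 profile")
  sites <- vapply(profiles, function(p) p$site, character(1))
  if (!all(sites == site))
    stopf("mixed site labels: expected all '%s'", site)
  d <- unlist(lapply(profiles, function(p) p$distance_nm))
  structure(list(arclength_nm = NULL, distance_nm = d,
                 mean_nm = mean(d), se_nm = stats::sd(d) / sqrt(length(d)),
                 n = length(d), site = site, n_profiles = length(profiles)),
            class = "distance_profile")
}
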