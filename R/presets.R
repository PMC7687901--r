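# Preset constructors for the synthetic-data generators. Defaults mirror the
# study conditions: murine atria paced at 100 ms cycle length, optical maps at
# 1000 frames/s, ECG digitized at 1 kHz, STORM-scale localization precision
# (20 nm lateral / 50 nm axial), and control intermembrane spacing of 17 nm
# at GJ-adjacent perinexal sites (64 nm after VEGF).

#' Preset for synthetic optical voltage maps
#'
#' Describes a propagating atrial action-potential wave as seen by a
#' voltage-sensitive dye camera: target conduction velocity, fast-axis
#' direction, anisotropy, action-potential duration, sampling, and noise.
#'
#' @param cv_cm_per_s conduction speed along the fast axis (cm/s).
#' @param fast_axis_deg propagation direction of the fast axis (degrees,
#'   0 = +x i.e. along columns).
#' @param anisotropy_ratio fast/slow CV ratio, >= 1. Used by the elliptical
#'   wave geometry; a planar wave propagates at `cv_cm_per_s` regardless.
#' @param apd_ms action-potential duration (ms).
#' @param frame_interval_ms sampling period (ms); 1 ms = 1000 frames/s.
#' @param pixel_size_um spatial sampling (micrometres per pixel).
#' @param grid_shape integer c(rows, cols).
#' @param snr upstroke amplitude divided by noise SD; `Inf` for noiseless.
#' @param signal_polarity +1 or -1; -1 models dyes whose fluorescence falls
#'   on depolarization (di-4-ANEPPS convention), the default.
#' @param geometry "planar", "elliptical" (remote point stimulus with
#'   anisotropic speeds, a curved front), or "quadratic" (curved front whose
#'   activation-time field is exactly quadratic; paraxial limit of a distant
#'   stimulus).
#' @return object of class `wave_preset`.
#' @export
wave_preset <- function(cv_cm_per_s = 21, fast_axis_deg = 0,
                        anisotropy_ratio = 2, apd_ms = 25,
                        frame_interval_ms = 1, pixel_size_um = 100,
                        grid_shape = c(32L, 32L), snr = 20,
                        signal_polarity = -1,
                        geometry = c("planar", "elliptical", "quadratic")) {
  geometry <- match.arg(geometry)
  check_scalar_pos(cv_cm_per_s, "cv_cm_per_s")
  check_scalar_pos(frame_interval_ms, "frame_interval_ms")
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  check_scalar_pos(apd_ms, "apd_ms")
  if (anisotropy_ratio < 1) stopf("`anisotropy_ratio` must be >= 1")
  if (!signal_polarity %in% c(-1, 1)) stopf("`signal_polarity` must be +1 or -1")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 4L))
    stopf("`grid_shape` must be c(rows, cols), each >= 4")
  if (!(is.infinite(snr) || snr > 0)) stopf("`snr` must be positive or Inf")
  # wave must stay resolvable: transit across the grid >= 10 frames
  extent_mm <- min(grid_shape) * pixel_size_um / 1000
  transit_ms <- extent_mm / (cv_cm_per_s / 100)
  if (transit_ms < 10 * frame_interval_ms)
    stopf("grid too small: wave transit %.1f ms is < 10 frames", transit_ms)
  structure(list(cv_cm_per_s = cv_cm_per_s, fast_axis_deg = fast_axis_deg,
                 anisotropy_ratio = anisotropy_ratio, apd_ms = apd_ms,
                 frame_interval_ms = frame_interval_ms,
                 pixel_size_um = pixel_size_um, grid_shape = grid_shape,
                 snr = snr, signal_polarity = signal_polarity,
                 geometry = geometry),
            class = "wave_preset")
}

#' Preset for synthetic murine ECG traces
#'
#' @param sampling_hz sampling rate (Hz), >= 500.
#' @param heart_rate_bpm sinus rate (beats/min).
#' @param p_duration_ms P-wave duration (ms).
#' @param pr_ms PR interval, P onset to QRS onset (ms); must exceed
#'   `p_duration_ms`.
#' @param qrs_ms QRS duration (ms).
#' @param noise_sd_mv additive Gaussian noise SD (mV).
#' @param episodes list of `c(start_s, duration_s)` arrhythmia intervals;
#'   within an episode sinus beats are replaced by irregular atrial
#'   deflections at roughly twice the sinus rate.
#' @param observation_s total trace length (s).
#' @param pacing list `c(start_s, end_s, cycle_ms)` for an optional burst
#'   pacing train rendered as stimulus artifacts, or `NULL`.
#' @return object of class `ecg_preset`.
#' @export
ecg_preset <- function(sampling_hz = 1000, heart_rate_bpm = 450,
                       p_duration_ms = 12, pr_ms = 40, qrs_ms = 10,
                       noise_sd_mv = 0.02, episodes = list(),
                       observation_s = 60, pacing = NULL) {
  if (sampling_hz < 500) stopf("`sampling_hz` must be >= 500")
  check_scalar_pos(heart_rate_bpm, "heart_rate_bpm")
  check_scalar_pos(p_duration_ms, "p_duration_ms")
  check_scalar_pos(observation_s, "observation_s")
  check_scalar_nonneg(noise_sd_mv, "noise_sd_mv")
  if (p_duration_ms >= pr_ms) stopf("`p_duration_ms` must be < `pr_ms`")
  if (length(episodes)) {
    ep <- do.call(rbind, lapply(episodes, as.numeric))
    if (ncol(ep) != 2L) stopf("each episode must be c(start_s, duration_s)")
    if (any(ep[, 1L] < 0) || any(ep[, 1L] + ep[, 2L] > observation_s))
      stopf("episodes must lie within [0, observation_s]")
    o <- order(ep[, 1L])
    ep <- ep[o, , drop = FALSE]
    if (nrow(ep) > 1L && any(ep[-nrow(ep), 1L] + ep[-nrow(ep), 2L] > ep[-1L, 1L]))
      stopf("overlapping episodes are not allowed")
    episodes <- lapply(seq_len(nrow(ep)), function(i) ep[i, ])
  }
  structure(list(sampling_hz = sampling_hz, heart_rate_bpm = heart_rate_bpm,
                 p_duration_ms = p_duration_ms, pr_ms = pr_ms, qrs_ms = qrs_ms,
                 noise_sd_mv = noise_sd_mv, episodes = episodes,
                 observation_s = observation_s, pacing = pacing),
            class = "ecg_preset")
}

#' Preset for synthetic intercalated-disk point clouds
#'
#' Three-channel 3D localization scene: compact reference clusters of Cx43
#' (gap junction, GJ) on one half of the field and N-cadherin (mechanical
#' junction, MJ) on the other, plus a target channel (NaV1.5 or beta1) whose
#' molecules are split between the 100 nm shells around GJ clusters, the
#' shells around MJ clusters, and the remainder of the ID volume with
#' controlled fractions. Control-like defaults put 59% of the target within
#' GJ shells and 35% within MJ shells.
#'
#' @param field_nm numeric c(x, y, z) bounding box (nm).
#' @param n_ref_gj,n_ref_mj number of GJ / MJ reference clusters.
#' @param ref_cluster_radius_nm radius of the compact reference blobs (nm).
#' @param ref_molecules_per_cluster localizations per reference cluster.
#' @param target_channel "NaV1.5" or "beta1".
#' @param n_target_molecules total target localizations.
#' @param frac_near_gj,frac_near_mj ground-truth fractions of the target
#'   placed within `shell_nm` of GJ / MJ clusters; must sum to <= 1. Ignored
#'   when `density_ratio_gj` is given.
#' @param density_ratio_gj,density_ratio_mj optional target in-shell /
#'   out-of-shell density ratios; when supplied the fractions are derived
#'   from the realized shell volumes so the emitted cloud has those ratios.
#' @param shell_nm proximity shell radius (nm), default 100.
#' @param loc_precision_xy_nm,loc_precision_z_nm localization jitter SD per
#'   axis (nm); defaults 20 lateral, 50 axial.
#' @param uniform_targets if `TRUE`, targets are placed uniformly over the
#'   field (homogeneous Poisson control) and labels are assigned afterwards
#'   from the realized geometry.
#' @return object of class `id_cloud_preset`.
#' @export
id_cloud_preset <- function(field_nm = c(3000, 1500, 400),
                            n_ref_gj = 10L, n_ref_mj = 10L,
                            ref_cluster_radius_nm = 100,
                            ref_molecules_per_cluster = 50L,
                            target_channel = c("NaV1.5", "beta1"),
                            n_target_molecules = 10000L,
                            frac_near_gj = 0.59, frac_near_mj = 0.35,
                            density_ratio_gj = NULL, density_ratio_mj = NULL,
                            shell_nm = 100,
                            loc_precision_xy_nm = 20, loc_precision_z_nm = 50,
                            uniform_targets = FALSE) {
  target_channel <- match.arg(target_channel)
  field_nm <- as.numeric(field_nm)
  if (length(field_nm) != 3L || any(field_nm <= 0)) stopf("`field_nm` must be 3 positive lengths")
  check_scalar_pos(shell_nm, "shell_nm")
  check_scalar_nonneg(loc_precision_xy_nm, "loc_precision_xy_nm")
  check_scalar_nonneg(loc_precision_z_nm, "loc_precision_z_nm")
  if (frac_near_gj < 0 || frac_near_mj < 0 || frac_near_gj + frac_near_mj > 1 + 1e-12)
    stopf("`frac_near_gj` + `frac_near_mj` must be in [0, 1]")
  # field must host non-overlapping GJ/MJ halves with shell margins
  need <- 4 * (ref_cluster_radius_nm + shell_nm)
  if (field_nm[1L] < need)
    stopf("field x-extent %.0f nm too small for disjoint GJ/MJ regions (need >= %.0f)",
          field_nm[1L], need)
  if (field_nm[2L] < 2 * ref_cluster_radius_nm || field_nm[3L] < 2 * ref_cluster_radius_nm)
    stopf("field y/z extent too small for reference clusters")
  structure(list(field_nm = field_nm, n_ref_gj = as.integer(n_ref_gj),
                 n_ref_mj = as.integer(n_ref_mj),
                 ref_cluster_radius_nm = ref_cluster_radius_nm,
                 ref_molecules_per_cluster = as.integer(ref_molecules_per_cluster),
                 target_channel = target_channel,
                 n_target_molecules = as.integer(n_target_molecules),
                 frac_near_gj = frac_near_gj, frac_near_mj = frac_near_mj,
                 density_ratio_gj = density_ratio_gj,
                 density_ratio_mj = density_ratio_mj,
                 shell_nm = shell_nm,
                 loc_precision_xy_nm = loc_precision_xy_nm,
                 loc_precision_z_nm = loc_precision_z_nm,
                 uniform_targets = isTRUE(uniform_targets)),
            class = "id_cloud_preset")
}

#' Preset for synthetic TEM membrane trace pairs
#'
#' Two apposed membrane traces whose perpendicular gap at arclength s is
#' `mean_gap_nm + gap_waviness_nm * sin(2*pi*s/length_nm)`. Defaults mimic
#' control GJ-adjacent perinexal spacing (17 nm); the VEGF-like condition is
#' obtained with `mean_gap_nm = 64`.
#'
#' @param length_nm trace length (nm).
#' @param mean_gap_nm mean intermembrane distance (nm).
#' @param gap_waviness_nm amplitude of the sinusoidal gap modulation (nm);
#'   must be < `mean_gap_nm`.
#' @param n_vertices vertices per trace.
#' @param angle_deg rigid rotation of the whole pair (degrees).
#' @param site "GJ-adjacent" or "MJ-adjacent" label carried through analysis.
#' @return object of class `membrane_preset`.
#' @export
membrane_preset <- function(length_nm = 1000, mean_gap_nm = 17,
                            gap_waviness_nm = 0, n_vertices = 200L,
                            angle_deg = 0,
                            site = c("GJ-adjacent", "MJ-adjacent")) {
  site <- match.arg(site)
  check_scalar_pos(length_nm, "length_nm")
  check_scalar_pos(mean_gap_nm, "mean_gap_nm")
  check_scalar_nonneg(gap_waviness_nm, "gap_waviness_nm")
  if (gap_waviness_nm >= mean_gap_nm)
    stopf("`mean_gap_nm` must exceed `gap_waviness_nm`")
  if (n_vertices < 2L) stopf("`n_vertices` must be >= 2")
  structure(list(length_nm = length_nm, mean_gap_nm = mean_gap_nm,
                 gap_waviness_nm = gap_waviness_nm,
                 n_vertices = as.integer(n_vertices),
                 angle_deg = angle_deg, site = site),
            class = "membrane_preset")
}
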