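# Synthetic murine ECG: sinus P-QRS-T morphology at a set heart rate with
# parameterized P-wave duration, optional burst-pacing artifact train, and
# insertable irregular atrial arrhythmia episodes with known burden.

#' Construct an ECG trace object
#'
#' @param samples voltage series (mV), uniformly sampled.
#' @param sampling_hz sampling rate (Hz), >= 500.
#' @param annotations list; recognized fields: `pacing_start_s`,
#'   `pacing_end_s`, `observation_s`.
#' @return object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, sampling_hz, annotations = list()) {
  if (sampling_hz < 500) stopf("`sampling_hz` must be >= 500")
  structure(list(samples = as.numeric(samples), sampling_hz = sampling_hz,
                 annotations = annotations),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %.1f s at %g Hz (%d samples)\n",
              length(x$samples) / x$sampling_hz, x$sampling_hz, length(x$samples)))
  invisible(x)
}

#' @export
plot.ecg_trace <- function(x, xlim = NULL, ...) {
  t <- seq_along(x$samples) / x$sampling_hz
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "mV",
                 xlim = xlim, ...)
  invisible(x)
}

# Add a shape (vector) into `samples` starting at time t0 (s); clipped to ends.
add_shape <- function(samples, fs, t0, shape) {
  i0 <- round(t0 * fs) + 1L
  idx <- i0:(i0 + length(shape) - 1L)
  keep <- idx >= 1L & idx <= length(samples)
  samples[idx[keep]] <- samples[idx[keep]] + shape[keep]
  samples
}

half_sine <- function(width_s, fs, amp) {
  n <- max(2L, round(width_s * fs))
  amp * sin(pi * (seq_len(n) - 0.5) / n)
}

triangle_pulse <- function(width_s, fs, amp, peak_frac = 0.4) {
  n <- max(3L, round(width_s * fs))
  p <- max(2L, round(peak_frac * n))
  amp * c(seq(0, 1, length.out = p), seq(1, 0, length.out = n - p + 1L)[-1L])
}

#' Generate a synthetic ECG trace
#'
#' Renders P/QRS/T complexes repeated at the sinus rate; within arrhythmia
#' episodes, sinus beats are replaced by irregular atrial deflections at
#' roughly twice the sinus rate whose inter-deflection intervals have a
#' coefficient of variation of 0.5 (gamma-jittered), making the episodes
#' detectable by interval statistics. An optional burst-pacing train is
#' rendered as large narrow stimulus artifacts.
#'
#' @param preset an [ecg_preset()].
#' @param seed integer seed (bit-determinism contract).
#' @return list with `trace` (an [ecg_trace()]) and `truth` (class
#'   `ground_truth`: sinus R times, true P duration, episode list, episode
#'   deflection times, burden in s/h).
#' @export
gen_ecg_trace <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "ecg_preset"))
  fs <- preset$sampling_hz
  n <- round(preset$observation_s * fs)
  samples <- numeric(n)
  rr_s <- 60 / preset$heart_rate_bpm
  pr_s <- preset$pr_ms / 1000
  p_s <- preset$p_duration_ms / 1000
  qrs_s <- preset$qrs_ms / 1000

  ep <- if (length(preset$episodes)) do.call(rbind, preset$episodes) else
    matrix(numeric(0), 0L, 2L)
  in_episode <- function(t, pad = 0.02) {
    if (!nrow(ep)) return(rep(FALSE, length(t)))
    res <- rep(FALSE, length(t))
    for (i in seq_len(nrow(ep)))
      res <- res | (t >= ep[i, 1L] - pad & t <= ep[i, 1L] + ep[i, 2L] + pad)
    res
  }
  pac <- preset$pacing
  in_pacing <- function(t, pad = 0.02) {
    if (is.null(pac)) rep(FALSE, length(t))
    else t >= pac[1L] - pad & t <= pac[2L] + pad
  }

  p_onsets <- seq(0.05, preset$observation_s - rr_s, by = rr_s)
  r_times <- p_onsets + pr_s + 0.4 * qrs_s
  keep <- !in_episode(r_times, pad = 0.03) & !in_pacing(r_times, pad = 0.03)
  out <- with_local_seed(seed, {
    for (k in which(keep)) {
      t0 <- p_onsets[k]
      samples <- add_shape(samples, fs, t0, half_sine(p_s, fs, 0.1))
      samples <- add_shape(samples, fs, t0 + pr_s, triangle_pulse(qrs_s, fs, 1.0))
      samples <- add_shape(samples, fs, t0 + pr_s + qrs_s + 0.010,
                           half_sine(0.040, fs, 0.2))
    }
    if (!is.null(pac)) {
      st <- seq(pac[1L], pac[2L], by = pac[3L] / 1000)
      for (t0 in st) samples <- add_shape(samples, fs, t0, triangle_pulse(0.002, fs, 1.5, 0.5))
    }
    defl_times <- list()
    if (nrow(ep)) {
      base_int <- rr_s / 2
      for (i in seq_len(nrow(ep))) {
        # the episode interval is spanned exactly: deflections anchored at
        # both ends, gamma-jittered in between (interval CV 0.5)
        t <- ep[i, 1L]
        t_end <- ep[i, 1L] + ep[i, 2L]
        tims <- numeric(0)
        while (t < t_end - base_int / 2) {
          tims <- c(tims, t)
          # gamma jitter floored at a 50 ms atrial refractory period
          t <- t + max(0.05, base_int * stats::rgamma(1, shape = 4, rate = 4))
        }
        tims <- c(tims, t_end)
        for (t0 in tims) samples <- add_shape(samples, fs, t0, triangle_pulse(0.008, fs, 0.45, 0.5))
        defl_times[[i]] <- tims
      }
    }
    if (preset$noise_sd_mv > 0)
      samples <- samples + stats::rnorm(n, 0, preset$noise_sd_mv)
    list(samples = samples, defl_times = defl_times)
  })

  ann <- list(observation_s = preset$observation_s)
  if (!is.null(pac)) { ann$pacing_start_s <- pac[1L]; ann$pacing_end_s <- pac[2L] }
  burden <- if (nrow(ep)) sum(ep[, 2L]) * 3600 / preset$observation_s else 0
  truth <- structure(list(
    module = "ecg", preset = preset, seed = as.integer(seed),
    r_times_s = r_times[keep],
    p_duration_ms = preset$p_duration_ms,
    episodes = ep,
    episode_deflection_times_s = out$defl_times,
    burden_s_per_h = burden), class = "ground_truth")
  list(trace = ecg_trace(out$samples, fs, ann), truth = truth)
}
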