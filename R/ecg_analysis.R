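# ECG analysis: beat detection, P-wave duration by signal averaging, and
# post-burst-pacing arrhythmia classification with burden in seconds of
# arrhythmia per hour of observation.

#' Detect beats (R peaks or atrial deflections)
#'
#' Band-passes the trace (10-100 Hz Butterworth, zero-phase), then applies a
#' locally adaptive amplitude threshold (half the local envelope maximum,
#' floored at 4 robust noise SDs) with a 40 ms refractory period. During
#' arrhythmia episodes the smaller atrial deflections set the local envelope,
#' so they are detected alongside sinus R peaks.
#'
#' @param trace an [ecg_trace()].
#' @param window_s window (s) of the local-envelope threshold.
#' @param refractory_s minimum spacing between detections.
#' @return numeric vector of beat times (s).
#' @export
detect_beats <- function(trace, window_s = 1, refractory_s = 0.04) {
  stopifnot(inherits(trace, "ecg_trace"))
  fs <- trace$sampling_hz
  x <- trace$samples
  bf <- signal::butter(2, c(10, 100) / (fs / 2), type = "pass")
  env <- abs(signal::filtfilt(bf, x))
  # chunked local maxima -> per-sample adaptive threshold
  chunk <- max(1L, round(window_s * fs / 2))
  n <- length(env)
  nch <- ceiling(n / chunk)
  cid <- rep(seq_len(nch), each = chunk, length.out = n)
  cmax <- tapply(env, cid, max)
  local_max <- pmax(cmax, c(cmax[-1L], 0), c(0, cmax[-nch]))
  thr <- pmax(0.3 * local_max[cid], 4 * stats::mad(env))
  cand <- which(env > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[env[cand] >= env[cand - 1L] & env[cand] >= env[cand + 1L]]
  if (!length(cand)) stopf("no beats detected")
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if ((i - last) / fs >= refractory_s) { keep <- c(keep, i); last <- i }
    else if (env[i] > env[keep[length(keep)]]) { keep[length(keep)] <- i; last <- i }
  }
  keep / fs
}

#' Measure P-wave duration
#'
#' Selects sinus beats (both flanking intervals within 15% of the median
#' inter-beat interval), signal-averages a window preceding each R peak,
#' estimates the isoelectric baseline from the TP segment, and marks P onset
#' and offset where the averaged signal crosses baseline +/- `k` baseline
#' SDs around the P deflection peak.
#'
#' @param trace an [ecg_trace()].
#' @param beats beat times from [detect_beats()].
#' @param k threshold in baseline SDs (default 2).
#' @param search_pre_s,search_post_s window before/after the R peak (s).
#' @param min_beats minimum sinus beats required for averaging.
#' @return object of class `p_wave_measurement`: `duration_ms`, `onset_ms`
#'   and `offset_ms` relative to the R peak, `n_beats_averaged`,
#'   `n_skipped`.
#' @export
measure_p_wave <- function(trace, beats = detect_beats(trace), k = 2,
                           search_pre_s = 0.070, search_post_s = 0.010,
                           min_beats = 10L) {
  stopifnot(inherits(trace, "ecg_trace"))
  fs <- trace$sampling_hz
  x <- trace$samples
  if (length(beats) < 3L) stopf("need >= 3 beats to measure the P wave")
  iv <- diff(beats)
  med <- stats::median(iv)
  sinus <- rep(FALSE, length(beats))
  for (i in seq_along(beats)) {
    pre <- if (i > 1L) abs(iv[i - 1L] - med) / med < 0.15 else FALSE
    post <- if (i < length(beats)) abs(iv[i] - med) / med < 0.15 else FALSE
    sinus[i] <- pre && post
  }
  r_idx <- round(beats[sinus] * fs)
  npre <- round(search_pre_s * fs); npost <- round(search_post_s * fs)
  r_idx <- r_idx[r_idx - npre >= 1L & r_idx + npost <= length(x)]
  if (length(r_idx) < min_beats)
    stopf("only %d sinus beats available (< %d)", length(r_idx), min_beats)
  seg <- vapply(r_idx, function(i) x[(i - npre):(i + npost)], numeric(npre + npost + 1L))
  avg <- rowMeans(seg)
  meas <- p_bounds(avg, fs, npre, k)
  if (is.null(meas)) stopf("P wave not detected above noise in averaged beat")
  structure(list(duration_ms = meas$dur * 1000,
                 onset_ms = (meas$on - npre - 1L) / fs * 1000,
                 offset_ms = (meas$off - npre - 1L) / fs * 1000,
                 n_beats_averaged = length(r_idx),
                 n_skipped = sum(!sinus),
                 k = k), class = "p_wave_measurement")
}

# Locate P onset/offset in an averaged pre-R window. `avg` has the R peak at
# index npre + 1. Returns NULL if no P deflection rises above threshold.
p_bounds <- function(avg, fs, npre, k) {
  base_idx <- 1:max(3L, round(0.015 * fs))          # TP segment at window start
  base <- mean(avg[base_idx])
  bsd <- max(stats::sd(avg[base_idx]), 1e-9)
  thr <- k * bsd
  # P search region: after baseline segment, ending clear of the QRS onset
  lo <- max(base_idx) + 1L
  hi <- npre + 1L - round(0.008 * fs)
  if (hi <= lo) return(NULL)
  dev <- abs(avg - base)
  pk <- lo - 1L + which.max(dev[lo:hi])
  if (dev[pk] <= 2 * thr) return(NULL)
  on <- pk
  while (on > lo && dev[on - 1L] > thr) on <- on - 1L
  off <- pk
  while (off < hi && dev[off + 1L] > thr) off <- off + 1L
  # sub-sample threshold crossings by linear interpolation
  on_f <- if (on > 1L && dev[on] > dev[on - 1L])
    on - 1L + (thr - dev[on - 1L]) / (dev[on] - dev[on - 1L]) else as.numeric(on)
  off_f <- if (off < length(dev) && dev[off] > dev[off + 1L])
    off + (dev[off] - thr) / (dev[off] - dev[off + 1L]) else as.numeric(off)
  list(on = on, off = off, dur = (off_f - on_f) / fs)
}

#' @export
print.p_wave_measurement <- function(x, ...) {
  cat(sprintf("<p_wave_measurement> duration %.1f ms (R%+.0f..%+.0f ms), %d beats averaged, %d skipped\n",
              x$duration_ms, x$onset_ms, x$offset_ms, x$n_beats_averaged, x$n_skipped))
  invisible(x)
}

#' Classify post-pacing rhythm and quantify arrhythmia burden
#'
#' Scans inter-deflection intervals after the end of a burst-pacing train. An
#' episode is a maximal run of intervals, at least `min_episode_s` long,
#' whose local rate (rolling mean over `cv_window` intervals) exceeds
#' `rate_factor` times the pre-pacing sinus rate and whose interval
#' coefficient of variation over the run exceeds `cv_threshold`
#' (irregularity). Burden is total episode seconds scaled to one hour of the
#' annotated observation window.
#'
#' @param trace an [ecg_trace()].
#' @param pacing_end_s end of the pacing train (s); defaults to the trace
#'   annotation.
#' @param min_episode_s minimum episode duration for inducibility (s).
#' @param cv_threshold rolling interval-CV threshold.
#' @param rate_factor rate criterion relative to the sinus rate.
#' @param cv_window rolling window length (intervals).
#' @return object of class `arrhythmia_call`: `inducible`, `episodes`
#'   (matrix start_s/end_s), `burden_s_per_h`, `observation_s`, and the
#'   thresholds used.
#' @export
classify_post_pacing <- function(trace,
                                 pacing_end_s = trace$annotations$pacing_end_s,
                                 min_episode_s = 1, cv_threshold = 0.2,
                                 rate_factor = 1.2, cv_window = 10L) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (is.null(pacing_end_s)) stopf("`pacing_end_s` not given and not annotated on the trace")
  fs <- trace$sampling_hz
  total_s <- length(trace$samples) / fs
  obs_s <- total_s - pacing_end_s
  if (obs_s < 1) stopf("post-pacing window %.2f s is shorter than 1 s", obs_s)
  beats <- detect_beats(trace)
  pacing_start_s <- trace$annotations$pacing_start_s %||% pacing_end_s
  pre <- beats[beats < pacing_start_s - 0.05]
  post <- beats[beats > pacing_end_s + 0.05]
  sinus_rr <- if (length(pre) >= 4L) stats::median(diff(pre)) else
    stats::median(diff(post))
  episodes <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("start_s", "end_s")))
  if (length(post) >= cv_window + 1L) {
    iv <- diff(post)
    rate_fast <- roll_stat(iv, cv_window, mean) < sinus_rr / rate_factor
    r <- rle(rate_fast)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s0 <- starts[j]; s1 <- ends[j]
      # trim sinus-like intervals smeared in by the rolling window
      while (s0 < s1 && iv[s0] >= sinus_rr / rate_factor) s0 <- s0 + 1L
      while (s1 > s0 && iv[s1] >= sinus_rr / rate_factor) s1 <- s1 - 1L
      run_iv <- iv[s0:s1]
      run_cv <- stats::sd(run_iv) / mean(run_iv)
      t0 <- post[s0]
      t1 <- post[s1 + 1L]
      if (is.finite(run_cv) && run_cv > cv_threshold && t1 - t0 >= min_episode_s)
        episodes <- rbind(episodes, c(t0, t1))
    }
  }
  # burden is reported over the annotated observation window when available
  burden_obs <- trace$annotations$observation_s %||% obs_s
  burden <- if (nrow(episodes)) sum(episodes[, 2L] - episodes[, 1L]) * 3600 / burden_obs else 0
  structure(list(inducible = nrow(episodes) > 0L, episodes = episodes,
                 burden_s_per_h = burden, observation_s = obs_s,
                 config = list(min_episode_s = min_episode_s,
                               cv_threshold = cv_threshold,
                               rate_factor = rate_factor,
                               cv_window = cv_window)),
            class = "arrhythmia_call")
}

#' @export
print.arrhythmia_call <- function(x, ...) {
  cat(sprintf("<arrhythmia_call> inducible: %s; %d episode(s); burden %.1f s/h over %.1f s\n",
              x$inducible, nrow(x$episodes), x$burden_s_per_h, x$observation_s))
  invisible(x)
}

#' Inducibility counts per group
#'
#' @param calls named list of groups, each a list of `arrhythmia_call`s.
#' @return 2 x k integer matrix (rows inducible / not inducible) suitable for
#'   [fisher_exact()].
#' @export
arrhythmia_incidence <- function(calls) {
  if (!length(calls)) stopf("need at least one group")
  tab <- vapply(calls, function(g) {
    ind <- vapply(g, function(c) isTRUE(c$inducible), logical(1))
    c(inducible = sum(ind), not_inducible = sum(!ind))
  }, numeric(2))
  storage.mode(tab) <- "integer"
  tab
}
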