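# Double-threshold detection of submental EMG activity: the first selection
# criterion of the two-stage procedure. A segment opens when the envelope
# stays above the onset threshold (baseline mean + k_on * SD) for a minimum
# dwell, and closes when it stays below the lower offset threshold
# (baseline mean + k_off * SD) for a minimum dwell; nearby segments are
# merged and too-short segments dropped.

#' Double-threshold detector parameters
#'
#' @param baseline_window_s length of the window used to estimate baseline
#'   noise statistics, seconds.
#' @param k_on onset threshold multiplier (threshold = mu + k_on * sigma).
#' @param k_off offset threshold multiplier; must be below `k_on`
#'   (hysteresis).
#' @param min_above_s minimum dwell above the onset threshold to open a
#'   segment, seconds.
#' @param min_below_s minimum dwell below the offset threshold to close a
#'   segment, seconds.
#' @param min_duration_s segments shorter than this (after merging) are
#'   discarded, seconds.
#' @param max_gap_merge_s segments separated by less than this are merged,
#'   seconds.
#' @return a named list of class `double_threshold_params`.
#' @export
double_threshold_params <- function(baseline_window_s = 1, k_on = 3,
                                    k_off = 2.5, min_above_s = 0.05,
                                    min_below_s = 0.2, min_duration_s = 0.2,
                                    max_gap_merge_s = 0.2) {
  p <- list(baseline_window_s = baseline_window_s, k_on = k_on, k_off = k_off,
            min_above_s = min_above_s, min_below_s = min_below_s,
            min_duration_s = min_duration_s,
            max_gap_merge_s = max_gap_merge_s)
  if (any(unlist(p[c("baseline_window_s", "min_above_s", "min_below_s",
                     "min_duration_s")]) <= 0))
    stop("durations must be > 0", call. = FALSE)
  if (p$k_off >= p$k_on) stop("k_off must be < k_on", call. = FALSE)
  structure(p, class = "double_threshold_params")
}

#' Estimate baseline envelope statistics
#'
#' Baseline noise level is taken from the minimum-mean window of the stated
#' length (not simply the first second), so recordings that start
#' mid-activity are handled. Returns the mean and standard deviation of the
#' envelope within that window.
#'
#' @param envelope nonnegative EMG envelope samples in mV.
#' @param fs sampling rate in Hz.
#' @param baseline_window_s window length in seconds.
#' @return a list with elements `mu` and `sigma` (both mV, `sigma >= 0`).
#' @export
estimate_baseline <- function(envelope, fs, baseline_window_s = 1) {
  w <- max(2L, as.integer(round(baseline_window_s * fs)))
  n <- length(envelope)
  if (n < w)
    stop("recording shorter than the baseline window", call. = FALSE)
  cs <- c(0, cumsum(envelope))
  starts <- 1:(n - w + 1)
  means <- (cs[starts + w] - cs[starts]) / w
  i0 <- which.min(means)
  win <- envelope[i0:(i0 + w - 1)]
  list(mu = mean(win), sigma = stats::sd(win))
}

# Shared threshold rule. With degenerate sigma = 0 the onset comparison is
# strict, so a flat zero envelope yields no activity instead of everything.
dt_thresholds <- function(mu, sigma, k_on, k_off) {
  list(on = mu + k_on * sigma, off = mu + k_off * sigma,
       strict = sigma <= .Machine$double.eps)
}

#' Detect EMG activity segments (double-threshold detector)
#'
#' Opens a segment where the envelope meets the onset threshold continuously
#' for at least `min_above_s`; closes it where the envelope drops below the
#' offset threshold continuously for at least `min_below_s` (the segment
#' ends at the last sample before that quiet run). Segments separated by
#' less than `max_gap_merge_s` are then merged, and segments shorter than
#' `min_duration_s` discarded. For each remaining segment the time of the
#' envelope maximum (`t_emg_max`, earliest sample on ties), the envelope
#' peak and the envelope RMS are reported.
#'
#' @param envelope nonnegative EMG envelope samples in mV.
#' @param fs sampling rate in Hz.
#' @param params a [double_threshold_params()] list.
#' @param t0 time of the first sample, seconds.
#' @return a data.frame with one row per segment: `t_emg_start`, `t_emg_max`,
#'   `t_emg_end`, `peak_mV`, `rms_mV`, sorted and non-overlapping. Zero rows
#'   when no activity is found.
#' @export
detect_emg_activity <- function(envelope, fs, params = double_threshold_params(),
                                t0 = 0) {
  bl <- estimate_baseline(envelope, fs, params$baseline_window_s)
  th <- dt_thresholds(bl$mu, bl$sigma, params$k_on, params$k_off)
  n <- length(envelope)
  on_cond <- if (th$strict) envelope > th$on else envelope >= th$on
  off_cond <- envelope < th$off
  min_above_n <- max(1L, as.integer(round(params$min_above_s * fs)))
  min_below_n <- max(1L, as.integer(round(params$min_below_s * fs)))

  # 3-state run-length walk: 2 = above onset, 0 = below offset, 1 = between.
  state <- integer(n) + 1L
  state[on_cond] <- 2L
  state[!on_cond & off_cond] <- 0L
  r <- rle(state)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L

  seg_start <- integer(0); seg_end <- integer(0)
  active <- FALSE; cur_start <- NA_integer_
  for (k in seq_along(r$values)) {
    if (!active) {
      if (r$values[k] == 2L && r$lengths[k] >= min_above_n) {
        active <- TRUE
        cur_start <- run_start[k]
      }
    } else {
      if (r$values[k] == 0L && r$lengths[k] >= min_below_n) {
        seg_start <- c(seg_start, cur_start)
        seg_end <- c(seg_end, run_start[k] - 1L)
        active <- FALSE
      }
    }
  }
  if (active) { seg_start <- c(seg_start, cur_start); seg_end <- c(seg_end, n) }

  emg_segments_from_indices(seg_start, seg_end, envelope, fs, params, t0)
}

# Merge close raw segments, drop short ones, and attach envelope statistics.
# Shared by the optimized detector and usable on any index pairs.
emg_segments_from_indices <- function(seg_start, seg_end, envelope, fs,
                                      params, t0 = 0) {
  empty <- data.frame(t_emg_start = numeric(0), t_emg_max = numeric(0),
                      t_emg_end = numeric(0), peak_mV = numeric(0),
                      rms_mV = numeric(0))
  if (!length(seg_start)) return(empty)
  # merge gaps shorter than max_gap_merge_s
  ms <- seg_start[1]; me <- seg_end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(seg_start) > 1) {
    for (i in 2:length(seg_start)) {
      gap_s <- (seg_start[i] - me - 1) / fs
      if (gap_s < params$max_gap_merge_s) {
        me <- seg_end[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- seg_start[i]; me <- seg_end[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  # discard short segments
  keep <- (out_e - out_s) / fs >= params$min_duration_s
  out_s <- out_s[keep]; out_e <- out_e[keep]
  if (!length(out_s)) return(empty)
  t_max <- peak <- rms <- numeric(length(out_s))
  for (i in seq_along(out_s)) {
    seg <- envelope[out_s[i]:out_e[i]]
    imax <- which.max(seg)  # earliest sample on ties
    t_max[i] <- t0 + (out_s[i] + imax - 2) / fs
    peak[i] <- seg[imax]
    rms[i] <- sqrt(mean(seg^2))
  }
  data.frame(t_emg_start = t0 + (out_s - 1) / fs,
             t_emg_max = t_max,
             t_emg_end = t0 + (out_e - 1) / fs,
             peak_mV = peak, rms_mV = rms)
}
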