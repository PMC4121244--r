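# Stage-1 pairing and swallowing-parameter extraction. A swallow candidate
# is an EMG activity segment paired with a BI valley under the physiological
# precedence rule: submental muscle activity always commences before the
# drop in bioimpedance.

#' Pair EMG activity segments with BI valleys
#'
#' A (segment, valley) pair qualifies iff `t_emg_start <= t_bi_start`
#' (muscle activity precedes the BI drop) and
#' `t_bi_start <= t_emg_end + grace_s` (the drop begins during, or just
#' after, the activity). Each EMG segment yields at most one candidate — the
#' deepest qualifying valley — and each valley is used at most once
#' (segments are served in time order).
#'
#' @param segments EMG segments from [detect_emg_activity()], sorted.
#' @param valleys BI valleys from [detect_bi_valleys()], sorted.
#' @param grace_s pairing grace period after EMG activity ends, seconds.
#' @return a data.frame with one row per candidate holding all segment and
#'   valley columns, sorted by `t_bi_min`. Zero rows if nothing pairs.
#' @export
pair_candidates <- function(segments, valleys, grace_s = 0.5) {
  empty <- cbind(
    data.frame(t_emg_start = numeric(0), t_emg_max = numeric(0),
               t_emg_end = numeric(0), peak_mV = numeric(0),
               rms_mV = numeric(0)),
    data.frame(t_bi_start = numeric(0), t_bi_min = numeric(0),
               t_bi_end = numeric(0), bi_at_start = numeric(0),
               bi_at_min = numeric(0), bi_at_end = numeric(0),
               depth = numeric(0), descent_slope = numeric(0),
               ascent_slope = numeric(0)))
  if (is.null(segments) || nrow(segments) == 0 ||
      is.null(valleys) || nrow(valleys) == 0) return(empty)
  used <- rep(FALSE, nrow(valleys))
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    ok <- !used &
      segments$t_emg_start[i] <= valleys$t_bi_start &
      valleys$t_bi_start <= segments$t_emg_end[i] + grace_s
    if (!any(ok)) next
    j <- which(ok)[which.min(valleys$depth[ok])]   # deepest = most negative
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- cbind(segments[i, , drop = FALSE],
                                       valleys[j, , drop = FALSE])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$t_bi_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Names of the extracted swallowing parameters
#'
#' The first four are the swallowing-related parameters proper; the rest are
#' auxiliary shape features fed to the classifier alongside them.
#' @return character vector of feature column names.
#' @export
swallow_feature_names <- function() {
  c("max_laryngeal_elevation", "speed_laryngeal_elevation",
    "duration_preparation", "extent_laryngeal_closure",
    "emg_duration", "emg_peak_mV", "emg_rms_mV",
    "descent_duration", "ascent_duration",
    "descent_slope", "ascent_slope", "emg_to_valley_latency")
}

#' Extract swallowing-related parameters from candidates
#'
#' Computes, per candidate:
#' * `max_laryngeal_elevation` (ohm) = `bi_at_min - bi_at_start` — negative,
#'   since the BI drop is measured from its local start value;
#' * `speed_laryngeal_elevation` (ohm/s) =
#'   `(bi_at_min - bi_at_start) / (t_bi_min - t_bi_start)` — negative;
#' * `duration_preparation` (s) = `t_emg_start - t_bi_start` — negative when
#'   muscle activity precedes the BI drop (the physiological case);
#' * `extent_laryngeal_closure` (s) = `t_bi_end - t_bi_start`;
#' plus auxiliary shape features: EMG burst duration, envelope peak and RMS,
#' valley descent/ascent durations and mean slopes, and the EMG-to-valley
#' latency `t_bi_start - t_emg_start`.
#'
#' @param candidates data.frame from [pair_candidates()].
#' @return a data.frame of features, one row per candidate, columns as in
#'   [swallow_feature_names()].
#' @export
extract_features <- function(candidates) {
  with(candidates, data.frame(
    max_laryngeal_elevation = bi_at_min - bi_at_start,
    speed_laryngeal_elevation = (bi_at_min - bi_at_start) /
      (t_bi_min - t_bi_start),
    duration_preparation = t_emg_start - t_bi_start,
    extent_laryngeal_closure = t_bi_end - t_bi_start,
    emg_duration = t_emg_end - t_emg_start,
    emg_peak_mV = peak_mV,
    emg_rms_mV = rms_mV,
    descent_duration = t_bi_min - t_bi_start,
    ascent_duration = t_bi_end - t_bi_min,
    descent_slope = descent_slope,
    ascent_slope = ascent_slope,
    emg_to_valley_latency = t_bi_start - t_emg_start
  ))
}

#' Run the full two-stage swallow detector on a recording
#'
#' Composition of the pipeline: EMG high-pass and envelope, BI smoothing,
#' double-threshold EMG activity detection (first selection criterion),
#' PLA valley detection on the decimated smoothed BI (second criterion),
#' physiological pairing, parameter extraction, and SVM classification.
#'
#' @param rec an [embi_recording()].
#' @param model a trained [train_classifier()] model.
#' @param cfg a [default_pipeline_config()] list.
#' @return a data.frame of detected events sorted by `t_bi_min`: all
#'   candidate landmark columns, the feature columns, plus `score` (signed
#'   SVM margin, positive means swallow) and `decision`
#'   (`"swallow"`/`"nonswallow"`). Zero rows when nothing reaches stage 2.
#' @export
detect_swallows <- function(rec, model, cfg = default_pipeline_config()) {
  validate_recording(rec)
  cand <- stage1_candidates(rec, cfg)
  if (nrow(cand) == 0) {
    out <- cbind(cand, data.frame(score = numeric(0),
                                  decision = character(0)))
    return(out)
  }
  feats <- extract_features(cand)
  cls <- classify_candidates(model, feats)
  out <- cbind(cand, feats[setdiff(names(feats), names(cand))], cls)
  out[order(out$t_bi_min), , drop = FALSE]
}

#' Stage-1 candidates for a recording
#'
#' Runs preprocessing, EMG activity detection, BI valley detection and
#' pairing only (no classifier) — the physiological coincidence filter.
#'
#' @param rec an [embi_recording()].
#' @param cfg a [default_pipeline_config()] list.
#' @return candidate data.frame as from [pair_candidates()].
#' @export
stage1_candidates <- function(rec, cfg = default_pipeline_config()) {
  emg_f <- highpass_emg(rec$emg, rec$fs,
                        cutoff_hz = cfg$emg_highpass$cutoff_hz,
                        order = cfg$emg_highpass$order,
                        zero_phase = cfg$emg_highpass$zero_phase)
  env <- emg_envelope(emg_f, rec$fs,
                      lowpass_hz = cfg$emg_envelope$lowpass_hz,
                      order = cfg$emg_envelope$order)
  dt <- double_threshold_params(
    baseline_window_s = cfg$emg_detector$baseline_window_s,
    k_on = cfg$emg_detector$k_on, k_off = cfg$emg_detector$k_off,
    min_above_s = cfg$emg_detector$min_above_s,
    min_below_s = cfg$emg_detector$min_below_s,
    min_duration_s = cfg$emg_detector$min_duration_s,
    max_gap_merge_s = cfg$emg_detector$max_gap_merge_s)
  segments <- detect_emg_activity(env, rec$fs, dt, t0 = rec$t[1])

  bis <- smooth_bi(rec$bi, rec$fs, lowpass_hz = cfg$bi_lowpass$cutoff_hz,
                   order = cfg$bi_lowpass$order,
                   zero_phase = cfg$bi_lowpass$zero_phase)
  dec <- max(1L, as.integer(round(rec$fs / cfg$pla$fs_hz)))
  idx <- seq(1L, length(bis), by = dec)
  fs_pla <- rec$fs / dec
  segs <- pla_approximate(bis[idx], fs_pla, epsilon = cfg$pla$epsilon_ohm,
                          init_len = cfg$pla$init_len)
  vc <- valley_conditions(
    min_depth_ohm = cfg$valley$min_depth_ohm,
    min_total_s = cfg$valley$min_total_s,
    max_total_s = cfg$valley$max_total_s,
    min_descent_s = cfg$valley$min_descent_s,
    max_descent_slope_ohm_s = cfg$valley$max_descent_slope_ohm_s,
    flat_max_s = cfg$valley$flat_max_s,
    slope_flat_ohm_s = cfg$valley$slope_flat_ohm_s)
  valleys <- detect_bi_valleys(segs, bis[idx], fs_pla, vc, t0 = rec$t[1])

  pair_candidates(segments, valleys, grace_s = cfg$pairing$grace_s)
}
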