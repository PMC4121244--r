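# Pipeline configuration: every tunable of the detector in one nested list,
# serialized to/from flat dotted-key YAML. Ranges are validated at load time
# so a bad config fails before any signal is touched.

.config_ranges <- list(
  emg_highpass.cutoff_hz       = c(0.1, Inf),
  emg_highpass.order           = c(1, 8),
  emg_envelope.lowpass_hz      = c(0.1, Inf),
  emg_envelope.order           = c(1, 8),
  bi_lowpass.cutoff_hz         = c(0.1, Inf),
  bi_lowpass.order             = c(1, 8),
  emg_detector.baseline_window_s = c(0.1, 60),
  emg_detector.k_on            = c(0, 100),
  emg_detector.k_off           = c(0, 100),
  emg_detector.min_above_s     = c(1e-3, 10),
  emg_detector.min_below_s     = c(1e-3, 10),
  emg_detector.min_duration_s  = c(1e-3, 30),
  emg_detector.max_gap_merge_s = c(0, 10),
  pla.epsilon_ohm              = c(1e-4, 10),
  pla.fs_hz                    = c(10, 4000),
  pla.init_len                 = c(2, 1000),
  valley.min_depth_ohm         = c(1e-3, 100),
  valley.min_total_s           = c(0.01, 60),
  valley.max_total_s           = c(0.02, 120),
  valley.min_descent_s         = c(0.005, 60),
  valley.max_descent_slope_ohm_s = c(-1000, 0),
  valley.flat_max_s            = c(0, 10),
  valley.slope_flat_ohm_s      = c(0, 10),
  pairing.grace_s              = c(0, 30),
  classifier.cost              = c(1e-6, 1e6),
  classifier.threshold         = c(-1e6, 1e6)
)

#' Default pipeline configuration
#'
#' Returns the full set of tunable detector parameters with their defaults:
#' EMG high-pass (Butterworth order 4, 20 Hz, zero-phase — standard surface-
#' EMG conditioning), envelope low-pass (order 2, 10 Hz on the rectified
#' signal), BI smoothing (order 2, 5 Hz — laryngeal-elevation valleys are
#' sub-5 Hz events), the double-threshold EMG detector (onset at baseline
#' mean + 3 SD, offset at + 2.5 SD, with dwell, merge and minimum-duration
#' times), piecewise-linear-approximation settings (tolerance 0.05 ohm at an
#' analysis rate of 100 Hz), the physiological valley conditions (depth at
#' least 0.25 ohm, total duration 0.2-3 s, descent at least 0.08 s at a mean
#' slope steeper than -0.5 ohm/s), the EMG-to-valley pairing grace (0.5 s),
#' and the SVM classifier settings (RBF kernel, C = 1, median-heuristic
#' kernel width, decision threshold 0).
#'
#' @return a nested named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  cfg <- list(
    emg_highpass = list(cutoff_hz = 20, order = 4, zero_phase = TRUE),
    emg_envelope = list(lowpass_hz = 10, order = 2),
    bi_lowpass   = list(cutoff_hz = 5, order = 2, zero_phase = TRUE),
    emg_detector = list(baseline_window_s = 1, k_on = 3, k_off = 2.5,
                        min_above_s = 0.05, min_below_s = 0.2,
                        min_duration_s = 0.2, max_gap_merge_s = 0.2),
    pla          = list(epsilon_ohm = 0.05, fs_hz = 100, init_len = 10),
    valley       = list(min_depth_ohm = 0.25, min_total_s = 0.2,
                        max_total_s = 3.0, min_descent_s = 0.08,
                        max_descent_slope_ohm_s = -0.5,
                        flat_max_s = 0.3, slope_flat_ohm_s = 0.05),
    pairing      = list(grace_s = 0.5),
    classifier   = list(cost = 1, gamma = NA_real_, threshold = 0)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

flatten_config <- function(cfg) {
  out <- list()
  for (grp in names(cfg)) {
    for (key in names(cfg[[grp]])) {
      out[[paste(grp, key, sep = ".")]] <- cfg[[grp]][[key]]
    }
  }
  out
}

#' Validate a pipeline configuration
#'
#' Every numeric parameter is checked against its documented range;
#' cross-parameter constraints (offset multiplier below onset multiplier,
#' minimum valley duration below maximum) are enforced too.
#'
#' @param cfg a `pipeline_config` list.
#' @return `cfg` unchanged, or an error naming the offending key.
#' @export
validate_pipeline_config <- function(cfg) {
  flat <- flatten_config(cfg)
  for (key in names(.config_ranges)) {
    v <- flat[[key]]
    if (is.null(v))
      stop("config is missing parameter ", key, call. = FALSE)
    rng <- .config_ranges[[key]]
    if (!is.numeric(v) || !is.finite(v) || v < rng[1] || v > rng[2])
      stop(sprintf("config parameter %s = %s outside allowed range [%g, %g]",
                   key, format(v), rng[1], rng[2]), call. = FALSE)
  }
  if (cfg$emg_detector$k_off >= cfg$emg_detector$k_on)
    stop("emg_detector.k_off must be < emg_detector.k_on", call. = FALSE)
  if (cfg$valley$min_total_s >= cfg$valley$max_total_s)
    stop("valley.min_total_s must be < valley.max_total_s", call. = FALSE)
  invisible(cfg)
  cfg
}

#' Read / write pipeline configuration as flat YAML
#'
#' The on-disk format is a flat key-value YAML file with dotted keys
#' (`emg_detector.k_on: 3`). Unknown keys are rejected; missing keys fall
#' back to package defaults.
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()]: a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  flat <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  known <- names(flatten_config(cfg))
  for (key in names(flat)) {
    if (!key %in% known)
      stop("unknown config parameter: ", key, call. = FALSE)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cfg[[parts[1]]][[parts[2]]] <- flat[[key]]
  }
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @return [write_pipeline_config()]: `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  yaml::write_yaml(flatten_config(cfg), path)
  invisible(path)
}
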