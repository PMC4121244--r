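#' Construct an EMBI recording
#'
#' An EMBI recording holds synchronized submental surface EMG (mV) and
#' cervical bioimpedance (ohm) sample streams on a single uniform time base.
#' During a swallow the submental muscles fire (EMG burst) and the pharyngeal
#' cavity closes with tissue, so bioimpedance drops; both channels together
#' carry the physiological signature the detector looks for.
#'
#' @param emg numeric vector of EMG samples in mV.
#' @param bi numeric vector of bioimpedance samples in ohm, same length.
#' @param fs sampling rate in Hz (> 0), common to both channels.
#' @param t0 time of the first sample in seconds (default 0).
#' @param subject_id opaque subject/recording identifier.
#' @param cohort_tag one of `"healthy"`, `"patient"`, `"unknown"`.
#' @return An object of class `embi_recording`: a list with elements
#'   `subject_id`, `fs`, `t`, `emg`, `bi`, `cohort_tag`.
#' @examples
#' rec <- embi_recording(emg = rnorm(1000, 0, 0.01),
#'                       bi = 10 + rnorm(1000, 0, 0.05), fs = 1000)
#' rec
#' @export
embi_recording <- function(emg, bi, fs, t0 = 0, subject_id = "anonymous",
                           cohort_tag = c("unknown", "healthy", "patient")) {
  cohort_tag <- match.arg(cohort_tag)
  rec <- structure(
    list(subject_id = as.character(subject_id),
         fs = as.numeric(fs),
         t = t0 + (seq_along(emg) - 1) / as.numeric(fs),
         emg = as.numeric(emg),
         bi = as.numeric(bi),
         cohort_tag = cohort_tag),
    class = "embi_recording")
  validate_recording(rec)
}

#' Validate an EMBI recording
#'
#' Checks the container invariants: both channels and the time vector share a
#' length of at least 2, the sampling rate is positive and matches the time
#' step to within 1 ppm relative jitter, and no sample is non-finite.
#'
#' @param rec an `embi_recording`.
#' @return `rec`, invisibly unchanged, or an error describing the violation.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "embi_recording"))
    stop("not an embi_recording", call. = FALSE)
  n <- length(rec$t)
  if (n < 2 || length(rec$emg) != n || length(rec$bi) != n)
    stop("recording channels must share a common length >= 2", call. = FALSE)
  if (!is.finite(rec$fs) || rec$fs <= 0)
    stop("sampling rate fs must be a positive finite number", call. = FALSE)
  if (anyNA(rec$emg) || any(!is.finite(rec$emg)))
    stop("non-finite values in column emg_mV", call. = FALSE)
  if (anyNA(rec$bi) || any(!is.finite(rec$bi)))
    stop("non-finite values in column bi_ohm", call. = FALSE)
  dt <- diff(rec$t)
  step <- 1 / rec$fs
  if (any(abs(dt - step) > 1e-6 * step))
    stop("non-uniform time base: relative jitter exceeds 1e-6", call. = FALSE)
  invisible(rec)
}

#' @export
print.embi_recording <- function(x, ...) {
  dur <- (length(x$t) - 1) / x$fs
  cat(sprintf("<embi_recording> subject=%s cohort=%s fs=%g Hz n=%d (%.1f s)\n",
              x$subject_id, x$cohort_tag, x$fs, length(x$t), dur))
  cat(sprintf("  emg [mV]:  range %.4g .. %.4g\n", min(x$emg), max(x$emg)))
  cat(sprintf("  bi  [ohm]: range %.4g .. %.4g\n", min(x$bi), max(x$bi)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `embi_recording`.
#' @return duration spanned by the samples, in seconds.
#' @export
recording_duration <- function(rec) (length(rec$t) - 1) / rec$fs
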