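# Channel conditioning ahead of detection. All filters are Butterworth IIR
# (signal::butter); zero-phase variants run forward-backward (filtfilt) so
# landmark times are not shifted. Filters are linear, time-invariant and
# length-preserving.

butter_apply <- function(x, fs, cutoff_hz, order, type, zero_phase = TRUE) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %g Hz must lie in (0, fs/2 = %g Hz)",
                 cutoff_hz, fs / 2), call. = FALSE)
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = type)
  if (!zero_phase) return(as.numeric(signal::filter(flt, x)))
  # odd (point-symmetric) reflection padding suppresses the start-up
  # transient of the zero-initial-condition forward-backward pass
  n <- length(x)
  npad <- min(n - 1, max(16L, as.integer(3 * round(fs / cutoff_hz))))
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(flt, c(left, x, right))
  y[(npad + 1):(npad + n)]
}

#' High-pass filter the EMG channel
#'
#' Removes DC offset, electrode drift and movement baseline from the raw
#' surface EMG so that the burst envelope reflects muscle activity only.
#' Default: Butterworth order 4, 20 Hz cutoff, zero-phase.
#'
#' @param x numeric EMG samples in mV, or an [embi_recording()] (its `emg`
#'   channel is used).
#' @param fs sampling rate in Hz (ignored when `x` is a recording).
#' @param cutoff_hz high-pass cutoff in Hz; must be below fs/2.
#' @param order filter order.
#' @param zero_phase forward-backward filtering (no phase shift) if `TRUE`.
#' @return filtered EMG samples, same length as the input.
#' @export
highpass_emg <- function(x, fs = NULL, cutoff_hz = 20, order = 4,
                         zero_phase = TRUE) {
  if (inherits(x, "embi_recording")) { fs <- x$fs; x <- x$emg }
  if (is.null(fs)) stop("fs is required for plain numeric input", call. = FALSE)
  butter_apply(x, fs, cutoff_hz, order, "high", zero_phase)
}

#' EMG amplitude envelope
#'
#' Full-wave rectification followed by a zero-phase low-pass (Butterworth
#' order 2, default 10 Hz), clamped at zero. The envelope is nonnegative and
#' scale-equivariant: scaling the input by c > 0 scales the envelope by c.
#'
#' @param emg_filtered high-pass filtered EMG samples in mV.
#' @param fs sampling rate in Hz.
#' @param lowpass_hz envelope smoothing cutoff in Hz; must be below fs/2.
#' @param order filter order.
#' @return nonnegative envelope samples, same length as input.
#' @export
emg_envelope <- function(emg_filtered, fs, lowpass_hz = 10, order = 2) {
  env <- butter_apply(abs(emg_filtered), fs, lowpass_hz, order, "low",
                      zero_phase = TRUE)
  pmax(env, 0)
}

#' Smooth the bioimpedance channel
#'
#' Zero-phase low-pass (Butterworth order 2, default 5 Hz) that suppresses
#' measurement noise while preserving the slow valley morphology of
#' laryngeal elevation: a 1 s wide, 1 ohm deep valley loses less than 5% of
#' its depth.
#'
#' @param bi bioimpedance samples in ohm, or an [embi_recording()].
#' @param fs sampling rate in Hz (ignored when `bi` is a recording).
#' @param lowpass_hz smoothing cutoff in Hz; must be below fs/2.
#' @param order filter order.
#' @param zero_phase forward-backward filtering if `TRUE`.
#' @return smoothed BI samples in ohm, same length as input.
#' @export
smooth_bi <- function(bi, fs = NULL, lowpass_hz = 5, order = 2,
                      zero_phase = TRUE) {
  if (inherits(bi, "embi_recording")) { fs <- bi$fs; bi <- bi$bi }
  if (is.null(fs)) stop("fs is required for plain numeric input", call. = FALSE)
  butter_apply(bi, fs, lowpass_hz, order, "low", zero_phase)
}
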