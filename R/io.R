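# Interchange formats: recordings and annotations travel as headered CSV
# ('.' decimal), config as flat key-value YAML. Times are seconds, 0-based;
# annotation intervals are half-open [onset, offset).

#' Read an EMBI recording from CSV
#'
#' Expects a comma-separated text file with header columns `time_s`,
#' `emg_mV`, `bi_ohm`. The time base must be uniform (relative jitter of the
#' sample step below 1e-6) and all samples finite.
#'
#' @param path file path.
#' @param fs_expected optional sampling rate in Hz; if given, the rate
#'   implied by the time column must match it within 1 ppm.
#' @param subject_id,cohort_tag metadata attached to the returned recording.
#' @return a validated [embi_recording()].
#' @export
read_recording <- function(path, fs_expected = NULL, subject_id = NULL,
                           cohort_tag = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "emg_mV", "bi_ohm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("recording file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) < 2)
    stop("recording must contain at least 2 samples", call. = FALSE)
  tt <- as.numeric(df$time_s)
  if (anyNA(tt) || any(!is.finite(tt)))
    stop("non-finite values in column time_s", call. = FALSE)
  dt <- diff(tt)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > 1e-6 * step))
    stop("non-uniform time base: relative jitter exceeds 1e-6", call. = FALSE)
  fs <- 1 / step
  if (!is.null(fs_expected) && abs(fs - fs_expected) > 1e-6 * fs_expected)
    stop(sprintf("sampling rate %.6g Hz does not match expected %.6g Hz",
                 fs, fs_expected), call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  embi_recording(emg = df$emg_mV, bi = df$bi_ohm, fs = fs, t0 = tt[1],
                 subject_id = subject_id, cohort_tag = cohort_tag)
}

#' Write an EMBI recording to CSV
#'
#' Inverse of [read_recording()]; the round trip is lossless to better than
#' 1e-9 (full double precision is printed).
#'
#' @param rec a validated `embi_recording`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  df <- data.frame(time_s = rec$t, emg_mV = rec$emg, bi_ohm = rec$bi)
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read event annotations from CSV
#'
#' Annotations mark ground-truth events: header columns `label` (one of
#' `swallow`, `nonswallow`), `sublabel` (free text, e.g. `chew`,
#' `head_movement`), `onset_s`, `offset_s`. Events are returned sorted by
#' onset; same-label events must not overlap.
#'
#' @param path file path.
#' @return a `data.frame` with the four columns above, sorted by onset.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(label = "character",
                                       sublabel = "character"))
  validate_annotations(df)
}

#' Validate an annotation table
#'
#' @param df a data.frame with columns `label`, `sublabel`, `onset_s`,
#'   `offset_s`.
#' @return the table, sorted by onset, or an error.
#' @export
validate_annotations <- function(df) {
  need <- c("label", "sublabel", "onset_s", "offset_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(df$label %in% c("swallow", "nonswallow")))
    stop("annotation label must be 'swallow' or 'nonswallow'", call. = FALSE)
  if (any(!is.finite(df$onset_s)) || any(!is.finite(df$offset_s)))
    stop("non-finite annotation times", call. = FALSE)
  if (any(df$onset_s >= df$offset_s))
    stop("annotation onset_s must be strictly before offset_s", call. = FALSE)
  df <- df[order(df$onset_s, df$offset_s), , drop = FALSE]
  rownames(df) <- NULL
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, ]
    if (nrow(sub) > 1 &&
        any(sub$onset_s[-1] < sub$offset_s[-nrow(sub)] - 1e-12))
      stop("overlapping '", lab, "' annotations", call. = FALSE)
  }
  df
}

#' Write event annotations to CSV
#' @param events annotation data.frame (see [read_annotations()]).
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  events <- validate_annotations(events)
  old <- options(digits = 17); on.exit(options(old))
  out <- events
  out$onset_s <- format(out$onset_s, digits = 17, trim = TRUE,
                        scientific = FALSE)
  out$offset_s <- format(out$offset_s, digits = 17, trim = TRUE,
                         scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
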