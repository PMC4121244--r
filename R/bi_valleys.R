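# Bioimpedance valley detection: the second selection criterion. The
# smoothed BI trace is segmented by bottom-up piecewise linear approximation
# (PLA); valleys are maximal descending runs followed by ascending runs of
# line pieces, and must satisfy physiological conditions (depth, duration,
# descent slope) before they count as laryngeal-elevation candidates.

# Least-squares line fit over samples [i, j] using precomputed cumulative
# sums; returns slope/intercept in index units plus the max abs residual.
pla_fit <- function(y, cx, cx2, cy, cxy, i, j) {
  k <- j - i + 1
  sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
  sxx <- cx2[j + 1] - cx2[i]; sxy <- cxy[j + 1] - cxy[i]
  den <- sxx - sx * sx / k
  slope <- if (den > 0) (sxy - sx * sy / k) / den else 0
  intercept <- (sy - slope * sx) / k
  xs <- i:j
  res <- y[xs] - (intercept + slope * xs)
  list(slope = slope, intercept = intercept, err = max(abs(res)))
}

#' Piecewise linear approximation of a signal (bottom-up merge)
#'
#' Tiles the signal with short initial pieces and repeatedly merges the
#' adjacent pair whose merged least-squares line has the smallest maximum
#' absolute residual, while that residual stays within `epsilon`. The result
#' is a contiguous tiling by line segments, each within `epsilon` of the
#' signal (up to the greedy guarantee of bottom-up merging; initial pieces
#' are never split).
#'
#' @param bi_smoothed smoothed BI samples in ohm.
#' @param fs sampling rate of `bi_smoothed` in Hz.
#' @param epsilon maximum absolute residual allowed per segment, ohm.
#' @param init_len initial piece length in samples (>= 2).
#' @return a data.frame with one row per segment: `i_start`, `i_end`
#'   (1-based sample indices, inclusive; consecutive segments share their
#'   boundary sample count as `i_end + 1 == i_start` of the next),
#'   `slope` (ohm/s), `intercept` (ohm, value of the fitted line at
#'   `i_start`), `max_abs_err` (ohm).
#' @export
pla_approximate <- function(bi_smoothed, fs, epsilon = 0.05, init_len = 10) {
  stopifnot(epsilon > 0)
  y <- as.numeric(bi_smoothed)
  n <- length(y)
  if (n < 2) stop("signal must have at least 2 samples", call. = FALSE)
  init_len <- max(2L, as.integer(init_len))
  xs <- seq_len(n)
  cx <- c(0, cumsum(xs)); cx2 <- c(0, cumsum(xs^2))
  cy <- c(0, cumsum(y)); cxy <- c(0, cumsum(xs * y))

  starts <- seq(1L, n, by = init_len)
  if (length(starts) > 1 && n - starts[length(starts)] < 1L)
    starts <- starts[-length(starts)]  # avoid a trailing 1-sample piece
  ends <- c(starts[-1] - 1L, n)
  # an initial piece already violating epsilon is subdivided into 2-sample
  # pieces (zero residual), so the bound holds unconditionally
  if (init_len > 2L) {
    s2 <- integer(0); e2 <- integer(0)
    for (k in seq_along(starts)) {
      if (pla_fit(y, cx, cx2, cy, cxy, starts[k], ends[k])$err <= epsilon) {
        s2 <- c(s2, starts[k]); e2 <- c(e2, ends[k])
      } else {
        ss <- seq(starts[k], ends[k] - 1L, by = 2L)
        ee <- c(ss[-1] - 1L, ends[k])   # final piece has 2 or 3 samples
        s2 <- c(s2, ss); e2 <- c(e2, ee)
      }
    }
    starts <- s2; ends <- e2
  }
  m <- length(starts)
  nxt <- c(2:m, NA_integer_)[seq_len(m)]
  prv <- c(NA_integer_, seq_len(m - 1))[seq_len(m)]
  alive <- rep(TRUE, m)

  merge_cost <- function(i) {
    j <- nxt[i]
    if (is.na(j)) return(Inf)
    pla_fit(y, cx, cx2, cy, cxy, starts[i], ends[j])$err
  }
  cost <- vapply(seq_len(m), merge_cost, numeric(1))

  while (m > 1) {
    i <- which.min(cost)
    if (cost[i] > epsilon) break
    j <- nxt[i]
    ends[i] <- ends[j]
    alive[j] <- FALSE
    nxt[i] <- nxt[j]
    if (!is.na(nxt[i])) prv[nxt[i]] <- i
    cost[j] <- Inf
    cost[i] <- merge_cost(i)
    if (!is.na(prv[i])) cost[prv[i]] <- merge_cost(prv[i])
    m <- m - 1
  }

  idx <- which(alive)
  slope <- numeric(length(idx)); intercept <- numeric(length(idx))
  err <- numeric(length(idx))
  for (k in seq_along(idx)) {
    f <- pla_fit(y, cx, cx2, cy, cxy, starts[idx[k]], ends[idx[k]])
    slope[k] <- f$slope * fs                       # per-sample -> per-second
    intercept[k] <- f$intercept + f$slope * starts[idx[k]]
    err[k] <- f$err
  }
  data.frame(i_start = starts[idx], i_end = ends[idx],
             slope = slope, intercept = intercept, max_abs_err = err)
}

#' Physiological valley conditions
#'
#' A detected BI valley only counts as a laryngeal-elevation candidate if it
#' is deep enough, neither too brief nor too slow overall, and descends both
#' long enough and steeply enough. Defaults pass the reported healthy-swallow
#' morphology (depth about -1.4 ohm reached at about -5 ohm/s) with a wide
#' margin.
#'
#' @param min_depth_ohm minimum |depth| in ohm.
#' @param min_total_s,max_total_s allowed total valley duration, seconds.
#' @param min_descent_s minimum descent duration, seconds.
#' @param max_descent_slope_ohm_s upper bound on the mean descent slope
#'   (a negative number; the slope must be at or below it).
#' @param flat_max_s longest run of flat PLA segments tolerated inside a
#'   valley (e.g. a flat valley floor), seconds.
#' @param slope_flat_ohm_s absolute slope below which a PLA segment counts
#'   as flat, ohm/s.
#' @return a named list of class `valley_conditions`.
#' @export
valley_conditions <- function(min_depth_ohm = 0.25, min_total_s = 0.2,
                              max_total_s = 3.0, min_descent_s = 0.08,
                              max_descent_slope_ohm_s = -0.5,
                              flat_max_s = 0.3, slope_flat_ohm_s = 0.05) {
  if (min_total_s >= max_total_s)
    stop("min_total_s must be < max_total_s", call. = FALSE)
  if (min_depth_ohm <= 0) stop("min_depth_ohm must be > 0", call. = FALSE)
  structure(list(min_depth_ohm = min_depth_ohm, min_total_s = min_total_s,
                 max_total_s = max_total_s, min_descent_s = min_descent_s,
                 max_descent_slope_ohm_s = max_descent_slope_ohm_s,
                 flat_max_s = flat_max_s, slope_flat_ohm_s = slope_flat_ohm_s),
            class = "valley_conditions")
}

#' Detect condition-checked BI valleys from a PLA segmentation
#'
#' A valley is a maximal run of descending PLA segments followed by a
#' maximal run of ascending segments, with at most `flat_max_s` of flat
#' segments tolerated between and within the runs (a slow valley floor).
#' `t_bi_start` is the start of the descending run, `t_bi_end` the end of
#' the ascending run, and `t_bi_min` the time of the signal minimum between
#' them (earliest sample on ties). Depth is measured from the local start
#' value, `bi_at_min - bi_at_start`, and is negative; valleys failing any
#' [valley_conditions()] test are discarded.
#'
#' @param segments PLA segmentation from [pla_approximate()].
#' @param bi_smoothed the smoothed BI samples the segmentation was built on.
#' @param fs sampling rate of `bi_smoothed`, Hz.
#' @param cond a [valley_conditions()] list.
#' @param t0 time of the first sample, seconds.
#' @return a data.frame with one row per valley: `t_bi_start`, `t_bi_min`,
#'   `t_bi_end`, `bi_at_start`, `bi_at_min`, `bi_at_end`, `depth` (< 0),
#'   `descent_slope` (< 0), `ascent_slope` (> 0); sorted, non-overlapping.
#' @export
detect_bi_valleys <- function(segments, bi_smoothed, fs,
                              cond = valley_conditions(), t0 = 0) {
  empty <- data.frame(t_bi_start = numeric(0), t_bi_min = numeric(0),
                      t_bi_end = numeric(0), bi_at_start = numeric(0),
                      bi_at_min = numeric(0), bi_at_end = numeric(0),
                      depth = numeric(0), descent_slope = numeric(0),
                      ascent_slope = numeric(0))
  if (is.null(segments) || nrow(segments) == 0) return(empty)
  y <- as.numeric(bi_smoothed)
  dir <- ifelse(segments$slope < -cond$slope_flat_ohm_s, -1L,
                ifelse(segments$slope > cond$slope_flat_ohm_s, 1L, 0L))
  seg_dur <- (segments$i_end - segments$i_start) / fs
  ns <- nrow(segments)

  out <- list()
  k <- 1L
  while (k <= ns) {
    if (dir[k] != -1L) { k <- k + 1L; next }
    # descending run, tolerating short flats inside
    d_end <- k
    j <- k + 1L
    while (j <= ns) {
      if (dir[j] == -1L) { d_end <- j; j <- j + 1L; next }
      if (dir[j] == 0L) {
        # flat gap: allowed if short and followed by more descent
        g <- j
        while (g <= ns && dir[g] == 0L) g <- g + 1L
        if (g <= ns && dir[g] == -1L &&
            sum(seg_dur[j:(g - 1)]) <= cond$flat_max_s) {
          d_end <- g; j <- g + 1L; next
        }
      }
      break
    }
    # flat floor between descent and ascent
    a_start <- d_end + 1L
    floor_dur <- 0
    while (a_start <= ns && dir[a_start] == 0L) {
      floor_dur <- floor_dur + seg_dur[a_start]
      a_start <- a_start + 1L
    }
    if (a_start > ns || dir[a_start] != 1L || floor_dur > cond$flat_max_s) {
      k <- d_end + 1L; next
    }
    # ascending run, tolerating short flats inside
    a_end <- a_start
    j <- a_start + 1L
    while (j <= ns) {
      if (dir[j] == 1L) { a_end <- j; j <- j + 1L; next }
      if (dir[j] == 0L) {
        g <- j
        while (g <= ns && dir[g] == 0L) g <- g + 1L
        if (g <= ns && dir[g] == 1L &&
            sum(seg_dur[j:(g - 1)]) <= cond$flat_max_s) {
          a_end <- g; j <- g + 1L; next
        }
      }
      break
    }
    i_start <- segments$i_start[k]
    i_end <- segments$i_end[a_end]
    span <- y[i_start:i_end]
    i_min <- i_start + which.min(span) - 1L      # earliest on ties
    v <- valley_row(y, fs, t0, i_start, i_min, i_end)
    if (valley_passes(v, cond)) out[[length(out) + 1L]] <- v
    k <- a_end + 1L
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

valley_row <- function(y, fs, t0, i_start, i_min, i_end) {
  t_start <- t0 + (i_start - 1) / fs
  t_min <- t0 + (i_min - 1) / fs
  t_end <- t0 + (i_end - 1) / fs
  depth <- y[i_min] - y[i_start]
  data.frame(t_bi_start = t_start, t_bi_min = t_min, t_bi_end = t_end,
             bi_at_start = y[i_start], bi_at_min = y[i_min],
             bi_at_end = y[i_end], depth = depth,
             descent_slope = depth / (t_min - t_start),
             ascent_slope = (y[i_end] - y[i_min]) / (t_end - t_min))
}

valley_passes <- function(v, cond) {
  total <- v$t_bi_end - v$t_bi_start
  descent <- v$t_bi_min - v$t_bi_start
  descent > 0 && (v$t_bi_end - v$t_bi_min) > 0 &&
    -v$depth >= cond$min_depth_ohm &&
    total >= cond$min_total_s && total <= cond$max_total_s &&
    descent >= cond$min_descent_s &&
    v$descent_slope <= cond$max_descent_slope_ohm_s
}
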