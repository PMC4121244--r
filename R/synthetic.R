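# Synthetic EMBI recording generator. Emulates the statistical structure the
# detector assumes: swallows are an EMG burst commencing before a smooth,
# conforming BI valley whose depth/speed/preparation/closure parameters are
# drawn from the reported healthy and patient group distributions;
# nonswallow confounders are chew-like repetitive EMG bursts without a
# conforming valley, and head-movement BI excursions that are slow and long
# (and sometimes EMG-silent or EMG-late, so they fail the physiological
# filter; the rest must be rejected by the classifier).

# Location adjustment for an upper-truncated normal: find mu such that
# E[X | X <= cut, X ~ N(mu, sd)] equals the target mean, so sign truncation
# does not bias the simulated population away from the reported group means.
truncnorm_adjust_mu <- function(target, sd, cut) {
  if (target >= cut) stop("target mean must lie below the truncation point")
  trunc_mean <- function(mu) {
    a <- (cut - mu) / sd
    mu - sd * stats::dnorm(a) / stats::pnorm(a)
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 lower = target, upper = cut + 8 * sd, tol = 1e-10)$root
}

rtrunc_upper <- function(n, mu, sd, cut) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mu, sd)
    ok <- x <= cut
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

rtrunc_range <- function(n, mu, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mu, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Cohort specification for the synthetic generator
#'
#' Defaults encode the reported group parameter distributions: healthy
#' swallows have maximum laryngeal elevation (valley depth) of -1.416 ohm
#' (SD 0.482) reached at -4.963 ohm/s (SD 1.901), preparation time -0.192 s
#' (SD 0.512) and closure duration 0.935 s (SD 0.512); the patient regime
#' uses -1.170 ohm (SD 0.645), -4.253 ohm/s (SD 2.488), closure 0.955 s
#' (SD 0.219), with wider preparation-time variability (SD 0.9 s) and a
#' lower EMG signal-to-noise ratio (8 dB vs 20 dB) to emulate the harder
#' detection problem in disordered swallowing. Depth and speed are drawn
#' from location-adjusted upper-truncated normals so their truncated means
#' equal the nominal means exactly; preparation time is truncated to the
#' negative-preparation convention (EMG precedes the BI drop), which biases
#' its mean relative to the nominal value.
#'
#' @param regime `"healthy"` or `"patient"`.
#' @param ... overrides for any spec field (e.g. `n_swallows`, `emg_snr_db`).
#' @return a named list of class `cohort_spec`.
#' @export
cohort_spec <- function(regime = c("healthy", "patient"), ...) {
  regime <- match.arg(regime)
  spec <- list(
    regime = regime,
    depth_mean = -1.416, depth_sd = 0.482, depth_cut = -0.3,
    speed_mean = -4.963, speed_sd = 1.901, speed_cut = -0.4,
    prep_mean = -0.192, prep_sd = 0.512, prep_lo = -1.4, prep_hi = -0.05,
    closure_mean = 0.935, closure_sd = 0.512,
    closure_lo = 0.3, closure_hi = 2.9,
    emg_snr_db = 20,
    n_swallows = 30, n_nonswallows = 60,
    event_spacing_s = 5.5,
    fs = 1000,
    emg_noise_mv = 0.01, bi_noise_ohm = 0.05, bi_baseline_ohm = 10,
    head_emg_silent_p = 0.25, head_emg_amp_frac = 0.5,
    seed = NA_integer_
  )
  if (regime == "patient") {
    spec$depth_mean <- -1.170; spec$depth_sd <- 0.645
    spec$speed_mean <- -4.253; spec$speed_sd <- 2.488
    spec$prep_mean <- 0.022; spec$prep_sd <- 0.9
    spec$closure_mean <- 0.955; spec$closure_sd <- 0.219
    spec$emg_snr_db <- 8
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown))
    stop("unknown cohort_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec[names(dots)] <- dots
  if (spec$depth_mean >= 0 || spec$speed_mean >= 0)
    stop("depth_mean and speed_mean must be negative", call. = FALSE)
  if (spec$depth_sd < 0 || spec$speed_sd < 0 || spec$prep_sd < 0 ||
      spec$closure_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  # location adjustment so truncated means hit the nominal means
  spec$depth_mu_adj <- truncnorm_adjust_mu(spec$depth_mean, spec$depth_sd,
                                           spec$depth_cut)
  spec$speed_mu_adj <- truncnorm_adjust_mu(spec$speed_mean, spec$speed_sd,
                                           spec$speed_cut)
  structure(spec, class = "cohort_spec")
}

# Band-limited (20 Hz .. min(450, fs/2 - 1) Hz) unit-RMS noise carrier.
emg_carrier <- function(n, fs) {
  hi <- min(450, fs / 2 - 1)
  flt <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
  pad <- as.integer(round(0.25 * fs))
  x <- signal::filtfilt(flt, stats::rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  x / sqrt(mean(x^2))
}

trapezoid <- function(n, fs, rise_s = 0.1, fall_s = 0.15) {
  r <- max(1L, as.integer(round(rise_s * fs)))
  f <- max(1L, as.integer(round(fall_s * fs)))
  if (r + f >= n) { r <- max(1L, n %/% 3); f <- max(1L, n %/% 3) }
  c(seq(0, 1, length.out = r), rep(1, n - r - f), seq(1, 0, length.out = f))
}

raised_cosine_valley <- function(n_frag, fs, t_start, depth, descent, ascent) {
  tt <- (seq_len(n_frag) - 1) / fs
  y <- numeric(n_frag)
  t_min <- t_start + descent
  t_end <- t_min + ascent
  d <- tt >= t_start & tt < t_min
  a <- tt >= t_min & tt <= t_end
  y[d] <- depth * (1 - cos(pi * (tt[d] - t_start) / descent)) / 2
  y[a] <- depth * (1 + cos(pi * (tt[a] - t_min) / ascent)) / 2
  y
}

#' Synthesize one swallow event
#'
#' Draws the swallowing parameters from the cohort distributions, then
#' renders an EMG fragment (trapezoid-modulated band-limited noise burst
#' whose onset precedes the BI drop by |preparation time|, amplitude set by
#' `emg_snr_db` over the baseline noise level) and a BI fragment (smooth
#' asymmetric raised-cosine valley: descent duration = depth/speed, total
#' duration = closure). Uses the current R random-number state; seed the RNG
#' for reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `emg` and `bi` fragment vectors (fragment-relative;
#'   additive on top of baseline noise) and `truth`, a one-row data.frame of
#'   the drawn parameters and true landmark times (fragment-relative
#'   seconds): `label`, `sublabel`, `onset_s`, `offset_s`, `t_emg_start`,
#'   `t_emg_end`, `t_bi_start`, `t_bi_min`, `t_bi_end`, `depth`, `speed`,
#'   `prep`, `closure`.
#' @export
synth_swallow_event <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fs <- spec$fs
  depth <- rtrunc_upper(1, spec$depth_mu_adj, spec$depth_sd, spec$depth_cut)
  speed <- rtrunc_upper(1, spec$speed_mu_adj, spec$speed_sd, spec$speed_cut)
  prep <- rtrunc_range(1, spec$prep_mean, spec$prep_sd,
                       spec$prep_lo, spec$prep_hi)
  closure <- rtrunc_range(1, spec$closure_mean, spec$closure_sd,
                          spec$closure_lo, spec$closure_hi)
  descent <- depth / speed                    # both negative -> positive s
  if (descent > 2.7) { descent <- 2.7; speed <- depth / descent }
  if (closure < descent + 0.15) closure <- descent + 0.15
  ascent <- closure - descent

  pre_pad <- 0.3
  t_emg_start <- pre_pad
  t_bi_start <- pre_pad - prep                # prep < 0
  t_bi_min <- t_bi_start + descent
  t_bi_end <- t_bi_start + closure
  emg_dur <- -prep + closure * stats::runif(1, 0.5, 0.9)
  t_emg_end <- t_emg_start + emg_dur
  frag_dur <- max(t_bi_end, t_emg_end) + 0.4
  n <- as.integer(ceiling(frag_dur * fs))

  bi <- raised_cosine_valley(n, fs, t_bi_start, depth, descent, ascent)
  emg <- numeric(n)
  i0 <- as.integer(round(t_emg_start * fs)) + 1L
  i1 <- min(n, as.integer(round(t_emg_end * fs)))
  nb <- i1 - i0 + 1L
  amp <- spec$emg_noise_mv * 10^(spec$emg_snr_db / 20)
  emg[i0:i1] <- amp * emg_carrier(nb, fs) * trapezoid(nb, fs)

  truth <- data.frame(
    label = "swallow", sublabel = "swallow",
    onset_s = max(0, min(t_emg_start, t_bi_start) - 0.2),
    offset_s = max(t_bi_end, t_emg_end) + 0.2,
    t_emg_start = t_emg_start, t_emg_end = t_emg_end,
    t_bi_start = t_bi_start, t_bi_min = t_bi_min, t_bi_end = t_bi_end,
    depth = depth, speed = speed, prep = prep, closure = closure)
  list(emg = emg, bi = bi, truth = truth)
}

#' Synthesize one nonswallow confounder event
#'
#' Two kinds are emulated. `"chew"`: a train of 3-5 short EMG bursts with
#' only a small BI ripple (|depth| below the valley-depth condition), so the
#' physiological filter finds EMG activity but no conforming valley.
#' `"head_movement"`: a slow, long BI excursion (depth 0.4-2 ohm over
#' several seconds) accompanied, with probability `1 - head_emg_silent_p`,
#' by a weaker movement-artifact EMG burst; when that artifact precedes the
#' dip and the dip happens to satisfy the valley conditions, the event
#' passes stage 1 and must be rejected by the classifier — otherwise it is
#' already stopped by the physiological filter (EMG silent, EMG too late,
#' too slow, or too long).
#'
#' @param kind `"chew"` or `"head_movement"`.
#' @param spec a [cohort_spec()].
#' @return same structure as [synth_swallow_event()], with `label`
#'   `"nonswallow"` and `sublabel` equal to `kind`; the landmark and
#'   parameter columns describe the rendered excursion (NA where not
#'   applicable).
#' @export
synth_nonswallow_event <- function(kind = c("chew", "head_movement"), spec) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "cohort_spec"))
  fs <- spec$fs
  amp <- spec$emg_noise_mv * 10^(spec$emg_snr_db / 20)
  if (kind == "chew") {
    nb <- sample(3:5, 1)
    durs <- stats::runif(nb, 0.25, 0.4)
    gaps <- stats::runif(nb - 1, 0.25, 0.4)
    pre_pad <- 0.3
    starts <- pre_pad + cumsum(c(0, durs[-nb] + gaps))
    frag_dur <- starts[nb] + durs[nb] + 0.4
    n <- as.integer(ceiling(frag_dur * fs))
    emg <- numeric(n)
    for (k in seq_len(nb)) {
      i0 <- as.integer(round(starts[k] * fs)) + 1L
      i1 <- min(n, as.integer(round((starts[k] + durs[k]) * fs)))
      m <- i1 - i0 + 1L
      emg[i0:i1] <- amp * stats::runif(1, 0.7, 1.1) *
        emg_carrier(m, fs) * trapezoid(m, fs, 0.05, 0.05)
    }
    wob_amp <- stats::runif(1, 0.03, 0.1)
    wob_f <- stats::runif(1, 0.8, 1.5)
    tt <- (seq_len(n) - 1) / fs
    win <- sin(pi * tt / frag_dur)^2
    bi <- wob_amp * win * sin(2 * pi * wob_f * tt)
    truth <- data.frame(
      label = "nonswallow", sublabel = "chew",
      onset_s = max(0, pre_pad - 0.2), offset_s = frag_dur - 0.2,
      t_emg_start = starts[1], t_emg_end = starts[nb] + durs[nb],
      t_bi_start = NA_real_, t_bi_min = NA_real_, t_bi_end = NA_real_,
      depth = NA_real_, speed = NA_real_, prep = NA_real_,
      closure = NA_real_)
    return(list(emg = emg, bi = bi, truth = truth))
  }

  # head movement
  depth <- -stats::runif(1, 0.4, 2.0)
  descent <- stats::runif(1, 0.5, 1.6)
  ascent <- stats::runif(1, 0.7, 1.8)
  closure <- descent + ascent
  silent <- stats::runif(1) < spec$head_emg_silent_p
  emg_off <- if (silent) NA_real_ else
    max(-1.2, min(0.3, stats::rnorm(1, -0.6, 0.35)))
  pre_pad <- 0.3 + max(0, if (silent) 0 else -emg_off)
  t_bi_start <- pre_pad
  t_bi_min <- t_bi_start + descent
  t_bi_end <- t_bi_start + closure
  emg_dur <- if (silent) 0 else stats::runif(1, 0.8, 2.0)
  t_emg_start <- if (silent) NA_real_ else t_bi_start + emg_off
  t_emg_end <- if (silent) NA_real_ else t_emg_start + emg_dur
  frag_dur <- max(t_bi_end, if (silent) 0 else t_emg_end) + 0.4
  n <- as.integer(ceiling(frag_dur * fs))
  bi <- raised_cosine_valley(n, fs, t_bi_start, depth, descent, ascent)
  emg <- numeric(n)
  if (!silent) {
    i0 <- as.integer(round(t_emg_start * fs)) + 1L
    i1 <- min(n, as.integer(round(t_emg_end * fs)))
    m <- i1 - i0 + 1L
    emg[i0:i1] <- amp * spec$head_emg_amp_frac *
      emg_carrier(m, fs) * trapezoid(m, fs, 0.15, 0.2)
  }
  truth <- data.frame(
    label = "nonswallow", sublabel = "head_movement",
    onset_s = max(0, min(t_bi_start, if (silent) Inf else t_emg_start) - 0.2),
    offset_s = frag_dur - 0.2,
    t_emg_start = t_emg_start, t_emg_end = t_emg_end,
    t_bi_start = t_bi_start, t_bi_min = t_bi_min, t_bi_end = t_bi_end,
    depth = depth, speed = depth / descent, prep = NA_real_,
    closure = closure)
  list(emg = emg, bi = bi, truth = truth)
}

#' Generate an annotated synthetic benchmark
#'
#' Renders `n_recordings` recordings, each containing `spec$n_swallows`
#' swallow events and `spec$n_nonswallows` nonswallow confounders (half
#' chew, half head movement) in shuffled order, one per `event_spacing_s`
#' slot with a small start jitter, on top of baseline EMG noise and a
#' slowly drifting noisy BI baseline. Fully reproducible from `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param n_recordings number of recordings (>= 1).
#' @param seed integer RNG seed.
#' @return a list of length `n_recordings`; each element is a list with
#'   `recording` ([embi_recording()]), `annotations` (data.frame of
#'   label/sublabel/onset_s/offset_s) and `truth` (ground-truth data.frame
#'   with drawn parameters and absolute landmark times).
#' @export
generate_benchmark <- function(spec, n_recordings, seed) {
  stopifnot(inherits(spec, "cohort_spec"), n_recordings >= 1)
  set.seed(as.integer(seed))
  fs <- spec$fs
  n_ev <- spec$n_swallows + spec$n_nonswallows
  dur <- 2 + n_ev * spec$event_spacing_s + 2
  n <- as.integer(dur * fs)
  n_chew <- spec$n_nonswallows %/% 2
  n_head <- spec$n_nonswallows - n_chew

  lapply(seq_len(n_recordings), function(r) {
    kinds <- sample(c(rep("swallow", spec$n_swallows),
                      rep("chew", n_chew), rep("head_movement", n_head)))
    emg <- stats::rnorm(n, 0, spec$emg_noise_mv)
    tt <- (seq_len(n) - 1) / fs
    drift <- 0.04 * sin(2 * pi * tt / 37 + stats::runif(1, 0, 2 * pi)) +
      0.03 * sin(2 * pi * tt / 61 + stats::runif(1, 0, 2 * pi)) +
      0.02 * sin(2 * pi * tt / 101 + stats::runif(1, 0, 2 * pi))
    bi <- spec$bi_baseline_ohm + drift + stats::rnorm(n, 0, spec$bi_noise_ohm)

    truths <- vector("list", n_ev)
    for (k in seq_len(n_ev)) {
      ev <- if (kinds[k] == "swallow") synth_swallow_event(spec) else
        synth_nonswallow_event(kinds[k], spec)
      slot0 <- 2 + (k - 1) * spec$event_spacing_s + stats::runif(1, 0, 0.4)
      i0 <- as.integer(round(slot0 * fs)) + 1L
      i1 <- min(n, i0 + length(ev$emg) - 1L)
      m <- i1 - i0 + 1L
      emg[i0:i1] <- emg[i0:i1] + ev$emg[seq_len(m)]
      bi[i0:i1] <- bi[i0:i1] + ev$bi[seq_len(m)]
      tr <- ev$truth
      for (col in c("onset_s", "offset_s", "t_emg_start", "t_emg_end",
                    "t_bi_start", "t_bi_min", "t_bi_end"))
        tr[[col]] <- tr[[col]] + slot0
      truths[[k]] <- tr
    }
    truth <- do.call(rbind, truths)
    truth <- truth[order(truth$onset_s), , drop = FALSE]
    rownames(truth) <- NULL
    ann <- validate_annotations(
      truth[, c("label", "sublabel", "onset_s", "offset_s")])
    rec <- embi_recording(emg = emg, bi = bi, fs = fs,
                          subject_id = sprintf("%s_%02d", spec$regime, r),
                          cohort_tag = spec$regime)
    list(recording = rec, annotations = ann, truth = truth)
  })
}
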