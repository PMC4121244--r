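# Independent reference implementations used as oracles. These deliberately
# re-derive each result from the rule definitions by brute force (per-sample
# state machines, exhaustive enumeration) and share no code with the package
# implementations they check.

# --- double-threshold detector: literal per-sample state machine -----------
oracle_emg_segments <- function(envelope, fs, params) {
  n <- length(envelope)
  w <- max(2L, as.integer(round(params$baseline_window_s * fs)))
  cs <- c(0, cumsum(envelope))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  i0 <- which.min(means)
  win <- envelope[i0:(i0 + w - 1)]
  mu <- mean(win); sigma <- sd(win)
  thr_on <- mu + params$k_on * sigma
  thr_off <- mu + params$k_off * sigma
  strict <- sigma <= .Machine$double.eps
  na <- max(1L, as.integer(round(params$min_above_s * fs)))
  nb <- max(1L, as.integer(round(params$min_below_s * fs)))

  seg_start <- integer(0); seg_end <- integer(0)
  active <- FALSE; above <- 0L; below <- 0L; cur <- NA_integer_
  for (i in seq_len(n)) {
    on_i <- if (strict) envelope[i] > thr_on else envelope[i] >= thr_on
    off_i <- envelope[i] < thr_off
    if (!active) {
      above <- if (on_i) above + 1L else 0L
      if (above == na) {
        active <- TRUE; cur <- i - na + 1L; below <- 0L
      }
    } else {
      below <- if (off_i) below + 1L else 0L
      if (below == nb) {
        seg_start <- c(seg_start, cur)
        seg_end <- c(seg_end, i - nb)
        active <- FALSE; above <- 0L
      }
    }
  }
  if (active) { seg_start <- c(seg_start, cur); seg_end <- c(seg_end, n) }

  # merge gaps (< max_gap_merge_s of samples strictly between), then drop short
  if (length(seg_start) > 1) {
    ms <- seg_start[1]; me <- seg_end[1]; os <- integer(0); oe <- integer(0)
    for (i in 2:length(seg_start)) {
      if ((seg_start[i] - me - 1) / fs < params$max_gap_merge_s) {
        me <- seg_end[i]
      } else {
        os <- c(os, ms); oe <- c(oe, me); ms <- seg_start[i]; me <- seg_end[i]
      }
    }
    seg_start <- c(os, ms); seg_end <- c(oe, me)
  }
  keep <- (seg_end - seg_start) / fs >= params$min_duration_s
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]

  if (!length(seg_start))
    return(data.frame(t_emg_start = numeric(0), t_emg_max = numeric(0),
                      t_emg_end = numeric(0), peak_mV = numeric(0),
                      rms_mV = numeric(0)))
  rows <- lapply(seq_along(seg_start), function(i) {
    seg <- envelope[seg_start[i]:seg_end[i]]
    im <- which.max(seg)
    data.frame(t_emg_start = (seg_start[i] - 1) / fs,
               t_emg_max = (seg_start[i] + im - 2) / fs,
               t_emg_end = (seg_end[i] - 1) / fs,
               peak_mV = seg[im], rms_mV = sqrt(mean(seg^2)))
  })
  do.call(rbind, rows)
}

# --- valley detection: derivative-based local-minimum search ---------------
oracle_bi_valleys <- function(bi_smoothed, fs, cond) {
  y <- as.numeric(bi_smoothed)
  n <- length(y)
  k <- max(1L, as.integer(round(0.05 * fs)))
  slope <- rep(0, n)
  ix <- (k + 1):(n - k)
  slope[ix] <- (y[ix + k] - y[ix - k]) / (2 * k / fs)
  dir <- ifelse(slope < -cond$slope_flat_ohm_s, -1L,
                ifelse(slope > cond$slope_flat_ohm_s, 1L, 0L))
  flat_n <- as.integer(round(cond$flat_max_s * fs))

  res <- list()
  i <- 1L
  while (i <= n) {
    if (dir[i] != -1L) { i <- i + 1L; next }
    start <- i
    # descend, tolerating flat gaps up to flat_n followed by more descent
    j <- i
    repeat {
      while (j < n && dir[j + 1L] == -1L) j <- j + 1L
      g <- j
      while (g < n && dir[g + 1L] == 0L) g <- g + 1L
      if (g < n && dir[g + 1L] == -1L && (g - j) <= flat_n) j <- g + 1L
      else break
    }
    d_end <- j
    # flat floor
    g <- d_end
    while (g < n && dir[g + 1L] == 0L) g <- g + 1L
    if (g >= n || dir[g + 1L] != 1L || (g - d_end) > flat_n) {
      i <- d_end + 1L; next
    }
    # ascend, tolerating flat gaps
    j <- g + 1L
    repeat {
      while (j < n && dir[j + 1L] == 1L) j <- j + 1L
      g2 <- j
      while (g2 < n && dir[g2 + 1L] == 0L) g2 <- g2 + 1L
      if (g2 < n && dir[g2 + 1L] == 1L && (g2 - j) <= flat_n) j <- g2 + 1L
      else break
    }
    a_end <- j
    imin <- start + which.min(y[start:a_end]) - 1L
    t_s <- (start - 1) / fs; t_m <- (imin - 1) / fs; t_e <- (a_end - 1) / fs
    depth <- y[imin] - y[start]
    total <- t_e - t_s; descent <- t_m - t_s
    ok <- descent > 0 && (t_e - t_m) > 0 &&
      -depth >= cond$min_depth_ohm &&
      total >= cond$min_total_s && total <= cond$max_total_s &&
      descent >= cond$min_descent_s &&
      depth / descent <= cond$max_descent_slope_ohm_s
    if (ok) res[[length(res) + 1L]] <- data.frame(t_bi_min = t_m)
    i <- a_end + 1L
  }
  if (!length(res)) data.frame(t_bi_min = numeric(0)) else do.call(rbind, res)
}

# --- Mann-Whitney exact p: full enumeration over labelings -----------------
oracle_u_exact <- function(a, b) {
  n1 <- length(a)
  pool <- c(a, b)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2, function(ix) u_of(pool[ix], pool[-ix]))
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(u = u_obs, p = p)
}

# --- pairing: exhaustive qualifying-pair assignment ------------------------
oracle_pairs <- function(segments, valleys, grace_s) {
  qual <- which(outer(seq_len(nrow(segments)), seq_len(nrow(valleys)),
                      function(i, j)
                        segments$t_emg_start[i] <= valleys$t_bi_start[j] &
                        valleys$t_bi_start[j] <= segments$t_emg_end[i] + grace_s),
                arr.ind = TRUE)
  used <- rep(FALSE, nrow(valleys))
  out <- list()
  for (i in seq_len(nrow(segments))) {
    js <- qual[qual[, 1] == i, 2]
    js <- js[!used[js]]
    if (!length(js)) next
    j <- js[which.min(valleys$depth[js])]
    used[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(seg = i, val = j)
  }
  if (!length(out)) data.frame(seg = integer(0), val = integer(0))
  else do.call(rbind, out)
}

# --- fixture builders ------------------------------------------------------

# envelope-like trace: baseline noise envelope plus rectangular-ish bursts
make_burst_envelope <- function(dur_s = 8, fs = 1000, bursts = list(),
                                noise_sd = 0.01) {
  emg <- rnorm(dur_s * fs, 0, noise_sd)
  for (b in bursts) {
    i0 <- round(b$start * fs) + 1; i1 <- round(b$end * fs)
    emg[i0:i1] <- emg[i0:i1] + b$amp * sin(2 * pi * 80 * seq(i0, i1) / fs)
  }
  emg_envelope(highpass_emg(emg, fs), fs)
}

# smoothed BI trace with known raised-cosine valleys, at 100 Hz
make_valley_trace <- function(valleys, dur_s = 14, fs = 100,
                              noise_sd = 0.02) {
  y <- 10 + rnorm(dur_s * fs, 0, noise_sd)
  tt <- (seq_along(y) - 1) / fs
  for (v in valleys) {
    tm <- v$t_start + v$descent
    te <- tm + v$ascent
    d <- tt >= v$t_start & tt < tm
    a <- tt >= tm & tt <= te
    y[d] <- y[d] - v$depth * (1 - cos(pi * (tt[d] - v$t_start) / v$descent)) / 2
    y[a] <- y[a] - v$depth * (1 + cos(pi * (tt[a] - tm) / v$ascent)) / 2
  }
  smooth_bi(y, fs)
}

random_valley_spec <- function(n_valleys) {
  lapply(seq_len(n_valleys), function(k)
    list(t_start = 1.5 + (k - 1) * 4 + runif(1, 0, 0.8),
         depth = runif(1, 0.5, 2),
         descent = runif(1, 0.3, 1),
         ascent = runif(1, 0.4, 1.2)))
}
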