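test_that("drawn depth and speed are calibrated to the cohort means", {
  for (reg in c("healthy", "patient")) {
    spec <- cohort_spec(reg)
    set.seed(11)
    draws <- replicate(1000, {
      e <- synth_swallow_event(spec)
      c(e$truth$depth, e$truth$speed)
    })
    se_d <- spec$depth_sd / sqrt(1000)
    se_s <- spec$speed_sd / sqrt(1000)
    expect_lt(abs(mean(draws[1, ]) - spec$depth_mean), 3 * se_d)
    expect_lt(abs(mean(draws[2, ]) - spec$speed_mean), 3 * se_s)
    expect_true(all(draws[1, ] < 0))
    expect_true(all(draws[2, ] < 0))
  }
})

test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec("healthy", depth_mean = 0.5), "negative")
  expect_error(cohort_spec("healthy", depth_sd = -1), "deviations")
  expect_error(cohort_spec("healthy", no_such = 1), "unknown")
  spec <- cohort_spec("patient")
  expect_equal(spec$emg_snr_db, 8)
  expect_equal(spec$depth_mean, -1.170)
})

test_that("event synthesis is deterministic under a fixed RNG state", {
  spec <- cohort_spec("healthy")
  set.seed(5); e1 <- synth_swallow_event(spec)
  set.seed(5); e2 <- synth_swallow_event(spec)
  expect_identical(e1, e2)

  set.seed(6); n1 <- synth_nonswallow_event("head_movement", spec)
  set.seed(6); n2 <- synth_nonswallow_event("head_movement", spec)
  expect_identical(n1, n2)

  b1 <- generate_benchmark(cohort_spec("healthy", n_swallows = 3,
                                       n_nonswallows = 4), 2, seed = 12)
  b2 <- generate_benchmark(cohort_spec("healthy", n_swallows = 3,
                                       n_nonswallows = 4), 2, seed = 12)
  expect_identical(b1, b2)

  expect_error(synth_nonswallow_event("dance", spec))
})

test_that("true landmarks always fall inside the annotation interval", {
  bench <- generate_benchmark(cohort_spec("healthy", n_swallows = 8,
                                          n_nonswallows = 8), 2, seed = 13)
  for (b in bench) {
    tr <- b$truth
    for (col in c("t_emg_start", "t_emg_end", "t_bi_start", "t_bi_min",
                  "t_bi_end")) {
      ok <- is.na(tr[[col]]) |
        (tr[[col]] >= tr$onset_s & tr[[col]] <= tr$offset_s)
      expect_true(all(ok))
    }
    # annotations and truth agree
    expect_equal(nrow(b$annotations), nrow(tr))
    expect_equal(sum(b$annotations$label == "swallow"), 8)
  }
})

test_that("swallow counts are conserved across recordings", {
  bench <- generate_benchmark(cohort_spec("healthy", n_swallows = 10,
                                          n_nonswallows = 4), 3, seed = 14)
  total <- sum(sapply(bench, function(b)
    sum(b$annotations$label == "swallow")))
  expect_equal(total, 30)
})

test_that("healthy and patient regimes differ detectably in depth and speed", {
  draw_params <- function(reg, n, seed) {
    spec <- cohort_spec(reg)
    set.seed(seed)
    d <- t(replicate(n, {
      e <- synth_swallow_event(spec)
      c(e$truth$depth, e$truth$speed, e$truth$prep, e$truth$closure)
    }))
    data.frame(max_laryngeal_elevation = d[, 1],
               speed_laryngeal_elevation = d[, 2],
               duration_preparation = d[, 3],
               extent_laryngeal_closure = d[, 4])
  }
  h <- draw_params("healthy", 300, 7)
  p <- draw_params("patient", 300, 8)
  tab <- compare_groups(h, p)
  expect_lte(tab$p_two_sided[tab$parameter == "max_laryngeal_elevation"], 0.05)
  expect_lte(tab$p_two_sided[tab$parameter == "speed_laryngeal_elevation"], 0.05)
})

test_that("an EMG-silent head movement never produces a stage-1 candidate", {
  spec <- cohort_spec("healthy", head_emg_silent_p = 1)
  bench <- generate_benchmark(cohort_spec("healthy", n_swallows = 0,
                                          n_nonswallows = 8,
                                          head_emg_silent_p = 1),
                              1, seed = 15)
  b <- bench[[1]]
  heads <- b$truth[b$truth$sublabel == "head_movement", ]
  cand <- stage1_candidates(b$recording)
  for (i in seq_len(nrow(heads)))
    expect_false(any(cand$t_bi_min >= heads$onset_s[i] &
                       cand$t_bi_min < heads$offset_s[i]))
})
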