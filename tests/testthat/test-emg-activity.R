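test_that("baseline statistics come from the minimum-mean window", {
  bl <- estimate_baseline(rep(0.5, 3000), 1000)
  expect_equal(bl$mu, 0.5)
  expect_equal(bl$sigma, 0)

  set.seed(5)
  env <- make_burst_envelope(6, 1000,
                             list(list(start = 3, end = 4.5, amp = 0.2)))
  bl <- estimate_baseline(env, 1000)
  quiet_mean <- mean(env[1:2500])          # burst only starts at 3 s
  expect_lt(abs(bl$mu - quiet_mean), 0.2 * quiet_mean)
  # shift equivariance: adding a constant shifts mu by that constant
  bl2 <- estimate_baseline(env + 0.3, 1000)
  expect_equal(bl2$mu, bl$mu + 0.3, tolerance = 1e-9)
  expect_equal(bl2$sigma, bl$sigma, tolerance = 1e-9)

  expect_error(estimate_baseline(env[1:100], 1000, 1), "shorter")
})

test_that("a zero envelope yields no activity (degenerate sigma)", {
  expect_equal(nrow(detect_emg_activity(numeric(5000), 1000)), 0)
})

test_that("a single burst is segmented at its true boundaries", {
  set.seed(42)
  env <- make_burst_envelope(4, 1000,
                             list(list(start = 1.0, end = 1.6, amp = 0.2)))
  seg <- detect_emg_activity(env, 1000)
  expect_equal(nrow(seg), 1)
  expect_gte(seg$t_emg_start, 0.95); expect_lte(seg$t_emg_start, 1.05)
  expect_gte(seg$t_emg_end, 1.55); expect_lte(seg$t_emg_end, 1.70)
  expect_true(seg$t_emg_start < seg$t_emg_max)
  expect_lte(seg$t_emg_max, seg$t_emg_end)
  expect_gte(seg$peak_mV, seg$rms_mV)
  # naive per-sample oracle agrees exactly
  expect_equal(seg, oracle_emg_segments(env, 1000, double_threshold_params()))
})

test_that("burst separation beyond/below the merge gap splits/joins segments", {
  set.seed(43)
  p <- double_threshold_params()
  env_far <- make_burst_envelope(8, 1000,
                                 list(list(start = 1, end = 1.6, amp = 0.2),
                                      list(start = 3.6, end = 4.2, amp = 0.2)))
  env_near <- make_burst_envelope(8, 1000,
                                  list(list(start = 1, end = 1.6, amp = 0.2),
                                       list(start = 1.65, end = 2.25, amp = 0.2)))
  expect_equal(nrow(detect_emg_activity(env_far, 1000, p)), 2)
  expect_equal(nrow(detect_emg_activity(env_near, 1000, p)), 1)
  expect_equal(detect_emg_activity(env_far, 1000, p),
               oracle_emg_segments(env_far, 1000, p))
  expect_equal(detect_emg_activity(env_near, 1000, p),
               oracle_emg_segments(env_near, 1000, p))
})

test_that("optimized detector equals the naive oracle on random traces", {
  set.seed(1234)
  p <- double_threshold_params()
  for (rep in 1:20) {
    nb <- sample(0:3, 1)
    bursts <- lapply(seq_len(nb), function(k) {
      s <- 0.5 + (k - 1) * 2.5 + runif(1, 0, 0.6)
      list(start = s, end = s + runif(1, 0.3, 1.2),
           amp = runif(1, 0.05, 0.3))
    })
    env <- make_burst_envelope(8, 1000, bursts)
    expect_equal(detect_emg_activity(env, 1000, p),
                 oracle_emg_segments(env, 1000, p))
  }
})

test_that("raising the onset multiplier never increases the segment count", {
  set.seed(77)
  env <- make_burst_envelope(10, 1000,
                             list(list(start = 1, end = 1.8, amp = 0.05),
                                  list(start = 4, end = 4.6, amp = 0.15),
                                  list(start = 7, end = 7.9, amp = 0.3)))
  counts <- sapply(c(2, 3, 5, 8, 15), function(k) {
    p <- double_threshold_params(k_on = k, k_off = min(1.5, k - 0.5))
    nrow(detect_emg_activity(env, 1000, p))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("pure Gaussian noise rarely produces false segments", {
  set.seed(2024)
  env <- emg_envelope(highpass_emg(rnorm(60000, 0, 0.01), 1000), 1000)
  expect_lte(nrow(detect_emg_activity(env, 1000)), 1)
})
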