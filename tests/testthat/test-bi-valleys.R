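test_that("an exact line is approximated by a single segment", {
  fs <- 100
  tt <- (0:499) / fs
  segs <- pla_approximate(10 - 0.5 * tt, fs, epsilon = 0.01)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$slope, -0.5, tolerance = 1e-6)
  expect_equal(segs$i_start, 1)
  expect_equal(segs$i_end, 500)
})

test_that("a symmetric V splits into two pieces with the true slopes", {
  fs <- 1000
  tt <- (0:999) / fs
  y <- ifelse(tt <= 0.5, 10 - 2 * tt, 9 + 2 * (tt - 0.5))
  segs <- pla_approximate(y, fs, epsilon = 0.01)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$slope[1], -2, tolerance = 0.02 * 2)
  expect_equal(segs$slope[2], 2, tolerance = 0.02 * 2)
})

test_that("every segment respects the residual bound", {
  set.seed(31)
  for (eps in c(0.02, 0.05, 0.1)) {
    y <- 10 + 0.5 * sin(2 * pi * 0.5 * (0:999) / 100) + rnorm(1000, 0, 0.01)
    segs <- pla_approximate(y, 100, epsilon = eps)
    expect_true(all(segs$max_abs_err <= eps))
    # contiguous tiling
    expect_equal(segs$i_start[-1], segs$i_end[-nrow(segs)] + 1)
  }
})

test_that("segment count is non-increasing in the tolerance", {
  set.seed(32)
  y <- 10 + 0.5 * sin(2 * pi * 0.4 * (0:1499) / 100) + rnorm(1500, 0, 0.02)
  counts <- sapply(c(0.02, 0.05, 0.1), function(eps)
    nrow(pla_approximate(y, 100, epsilon = eps)))
  expect_true(all(diff(counts) <= 0))
})

test_that("a V-shaped drop is detected as one valley at the vertex", {
  fs <- 1000
  tt <- (0:1999) / fs
  y <- 10 + ifelse(tt < 0.5, 0, ifelse(tt <= 1, -2 * (tt - 0.5),
                                       ifelse(tt <= 1.5, -1 + 2 * (tt - 1), 0)))
  segs <- pla_approximate(y, fs, epsilon = 0.01)
  v <- detect_bi_valleys(segs, y, fs)
  expect_equal(nrow(v), 1)
  expect_lte(abs(v$t_bi_min - 1.0) * fs, 2)
  expect_lt(v$depth, 0)
  expect_lt(v$descent_slope, 0)
  expect_gt(v$ascent_slope, 0)

  # too-shallow V is filtered out by the depth condition
  y2 <- 10 + ifelse(tt < 0.5, 0, ifelse(tt <= 1, -0.2 * (tt - 0.5),
                                        ifelse(tt <= 1.5, -0.1 + 0.2 * (tt - 1), 0)))
  segs2 <- pla_approximate(y2, fs, epsilon = 0.01)
  v2 <- detect_bi_valleys(segs2, y2, fs,
                          valley_conditions(min_depth_ohm = 0.3))
  expect_equal(nrow(v2), 0)
})

test_that("a W-shaped trace yields two valleys, agreeing with the oracle", {
  set.seed(33)
  spec <- list(list(t_start = 2, depth = 1, descent = 0.5, ascent = 0.5),
               list(t_start = 6, depth = 1, descent = 0.4, ascent = 0.6))
  y <- make_valley_trace(spec, dur_s = 10, fs = 100)
  segs <- pla_approximate(y, 100, epsilon = 0.05)
  v <- detect_bi_valleys(segs, y, 100)
  expect_equal(nrow(v), 2)
  o <- oracle_bi_valleys(y, 100, valley_conditions())
  expect_equal(nrow(o), 2)
  expect_true(all(abs(v$t_bi_min - o$t_bi_min) * 100 <= 5))
})

test_that("valley detection agrees with the naive oracle on random traces", {
  set.seed(404)
  cond <- valley_conditions()
  for (rep in 1:20) {
    spec <- random_valley_spec(sample(1:3, 1))
    y <- make_valley_trace(spec, dur_s = 14, fs = 100)
    segs <- pla_approximate(y, 100, epsilon = 0.05)
    v <- detect_bi_valleys(segs, y, 100, cond)
    o <- oracle_bi_valleys(y, 100, cond)
    expect_equal(nrow(v), nrow(o))
    if (nrow(v)) expect_true(all(abs(v$t_bi_min - o$t_bi_min) * 100 <= 5))
  }
})

test_that("tightening the depth condition never increases the valley count", {
  set.seed(55)
  spec <- random_valley_spec(3)
  y <- make_valley_trace(spec, dur_s = 14, fs = 100)
  segs <- pla_approximate(y, 100, epsilon = 0.05)
  counts <- sapply(c(0.25, 0.6, 1.0, 1.8, 3), function(d)
    nrow(detect_bi_valleys(segs, y, 100,
                           valley_conditions(min_depth_ohm = d))))
  expect_true(all(diff(counts) <= 0))
})
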