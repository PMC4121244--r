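test_that("confusion table arithmetic and degenerate rates", {
  ct <- confusion_table(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(ct$sensitivity, 1)
  expect_equal(ct$specificity, 1)

  # counts whose rates mirror the reported patient-group operating point
  ct <- confusion_table(tp = 359, fp = 234, fn = 68, tn = 1293)
  expect_equal(round(100 * ct$sensitivity, 1), 84.1)
  expect_equal(round(100 * ct$specificity, 1), 84.7)
  expect_equal(round(100 * ct$accuracy, 1), 84.5)

  ct <- confusion_table(tp = 0, fp = 0, fn = 5, tn = 7)
  expect_equal(ct$sensitivity, 0)
  expect_equal(ct$specificity, 1)

  ct <- confusion_table(tp = 0, fp = 0, fn = 0, tn = 3)
  expect_true(is.na(ct$sensitivity))   # undefined, never reported as 0
  expect_error(confusion_table(-1, 0, 0, 0), "nonnegative")
})

truth_tab <- function() {
  data.frame(label = c("swallow", "nonswallow", "swallow", "nonswallow"),
             sublabel = c("swallow", "chew", "swallow", "head_movement"),
             onset_s = c(1, 4, 7, 10), offset_s = c(3, 6, 9, 12))
}

det_tab <- function(t, decision = "swallow")
  data.frame(t_bi_min = t, decision = rep(decision, length.out = length(t)))

test_that("event matching counts TP, FN, TN, FP by valley-minimum containment", {
  # perfect: both swallows hit, both nonswallows clean
  ct <- match_events(det_tab(c(2, 8)), truth_tab())
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(2, 0, 0, 2))

  # zero detections: sensitivity 0, specificity 100%
  ct <- match_events(det_tab(numeric(0)), truth_tab())
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(0, 0, 2, 2))
  expect_equal(ct$specificity, 1)

  # duplicate detection inside one swallow is a false positive
  ct <- match_events(det_tab(c(2, 2.5, 8)), truth_tab())
  expect_equal(c(ct$tp, ct$fp), c(2, 1))

  # a swallow decision inside a nonswallow interval flips that TN to FP
  ct <- match_events(det_tab(c(2, 5, 8)), truth_tab())
  expect_equal(c(ct$tp, ct$fp, ct$tn), c(2, 1, 1))

  # a stray detection outside every interval is a false positive
  ct <- match_events(det_tab(c(2, 8, 20)), truth_tab())
  expect_equal(ct$fp, 1)

  # nonswallow decisions are not counted against nonswallow intervals
  ct <- match_events(det_tab(c(2, 5, 8), c("swallow", "nonswallow", "swallow")),
                     truth_tab())
  expect_equal(c(ct$tp, ct$fp, ct$tn), c(2, 0, 2))
})

test_that("U test: worked examples and branch selection", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_two_sided, 0.1, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))   # ties -> normal approximation
  expect_identical(r$method, "normal_approx")
  expect_equal(r$p_two_sided, 1)

  r <- mann_whitney_u(1:8, 101:108)              # n > 12 -> approximation
  expect_identical(r$method, "normal_approx")
  expect_lt(r$p_two_sided, 0.001)

  r <- mann_whitney_u(2, 5)                      # minimal 1 vs 1 case
  expect_equal(r$p_two_sided, 1)

  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("exact branch equals brute-force enumeration for all n1, n2 <= 6", {
  set.seed(71)
  for (n1 in 1:6) for (n2 in 1:6) {
    x <- sample(seq(1, 100), n1 + n2)   # tie-free
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    got <- mann_whitney_u(a, b)
    want <- oracle_u_exact(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$u_statistic, want$u)
    expect_equal(got$p_two_sided, want$p, tolerance = 1e-12)
    expect_gte(got$u_statistic, 0)
    expect_lte(got$u_statistic, n1 * n2)
  }
})

test_that("type-I error of the U test is near the nominal 5% level", {
  set.seed(72)
  hits <- 0L
  for (r in 1:2000) {
    if (mann_whitney_u(rnorm(50), rnorm(50))$p_two_sided <= 0.05)
      hits <- hits + 1L
  }
  rate <- hits / 2000
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

draw_param_set <- function(n, depth_m, depth_s, speed_m, speed_s,
                           prep_m, prep_s, clos_m, clos_s) {
  data.frame(duration_preparation = rnorm(n, prep_m, prep_s),
             extent_laryngeal_closure = rnorm(n, clos_m, clos_s),
             max_laryngeal_elevation = rnorm(n, depth_m, depth_s),
             speed_laryngeal_elevation = rnorm(n, speed_m, speed_s))
}

test_that("group comparison flags the reported healthy/patient differences", {
  set.seed(7)
  healthy <- draw_param_set(300, -1.416, 0.482, -4.963, 1.901,
                            -0.192, 0.512, -0.935, 0.512)
  patient <- draw_param_set(300, -1.170, 0.645, -4.253, 2.488,
                            0.022, 0.9, -0.955, 0.219)
  tab <- compare_groups(healthy, patient)
  expect_equal(nrow(tab), 4)
  expect_lte(tab$p_two_sided[tab$parameter == "max_laryngeal_elevation"], 0.05)
  expect_lte(tab$p_two_sided[tab$parameter == "speed_laryngeal_elevation"], 0.05)
})

test_that("under the null, extreme p-values are as rare as they should be", {
  set.seed(7)
  small <- 0L
  for (r in 1:200) {
    a <- draw_param_set(50, -1.4, 0.5, -5, 1.9, -0.2, 0.5, -0.9, 0.5)
    b <- draw_param_set(50, -1.4, 0.5, -5, 1.9, -0.2, 0.5, -0.9, 0.5)
    p <- compare_groups(a, b)$p_two_sided
    small <- small + any(p <= 0.001)
  }
  expect_gte(200 - small, 198)   # p > 0.001 in at least 99% of repetitions

  one <- compare_groups(draw_param_set(1, -1.4, 0, -5, 0, -0.2, 0, -0.9, 0),
                        draw_param_set(1, -1.2, 0, -4, 0, -0.1, 0, -0.8, 0))
  expect_true(all(one$p_two_sided == 1))
})
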