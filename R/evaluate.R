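# Event-level evaluation: detections are scored against annotated truth via
# a 2x2 contingency table, and parameter distributions are compared between
# groups with the Mann-Whitney U test (two-sided, alpha = 0.05, no
# multiple-testing correction — four separate tests).

#' Build a confusion table
#'
#' @param tp,fp,fn,tn nonnegative integer counts.
#' @return an object of class `confusion_table` with the counts and the
#'   derived rates `sensitivity` = tp/(tp+fn), `specificity` = tn/(tn+fp),
#'   `accuracy` = (tp+tn)/total. A rate with zero denominator is `NA`,
#'   never 0.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 accuracy = rate(tp + tn, tp + fp + fn + tn)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity = %.1f%%  specificity = %.1f%%  accuracy = %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' Score detected events against annotations
#'
#' Event-level matching by valley-minimum containment: a detection with
#' decision "swallow" whose `t_bi_min` lies inside a truth swallow interval
#' is a true positive (one-to-one, greedy in time order; surplus detections
#' in the same interval are false positives). Unmatched truth swallows are
#' false negatives. A truth nonswallow interval containing no
#' swallow-decision detection is a true negative, with at least one a false
#' positive. Swallow-decision detections falling in no truth interval also
#' count as false positives.
#'
#' @param detected data.frame from [detect_swallows()] (columns `t_bi_min`,
#'   `decision`), or a stage-1 candidate table plus `decision`.
#' @param truth annotation data.frame (see [read_annotations()]) containing
#'   both swallow and nonswallow events.
#' @return a [confusion_table()].
#' @export
match_events <- function(detected, truth) {
  truth <- validate_annotations(truth)
  sw <- truth[truth$label == "swallow", , drop = FALSE]
  ns <- truth[truth$label == "nonswallow", , drop = FALSE]
  det_t <- if (nrow(detected)) detected$t_bi_min[detected$decision == "swallow"]
           else numeric(0)
  det_t <- sort(det_t)

  matched_sw <- rep(FALSE, nrow(sw))
  det_used <- rep(FALSE, length(det_t))
  for (k in seq_along(det_t)) {           # greedy, in time order
    hit <- which(!matched_sw & sw$onset_s <= det_t[k] &
                   det_t[k] < sw$offset_s)
    if (length(hit)) { matched_sw[hit[1]] <- TRUE; det_used[k] <- TRUE }
  }
  tp <- sum(matched_sw)
  fn <- sum(!matched_sw)

  in_ns <- vapply(det_t, function(tt)
    any(ns$onset_s <= tt & tt < ns$offset_s), logical(1))
  fp_ns_events <- if (nrow(ns)) sum(vapply(seq_len(nrow(ns)), function(i)
    any(!det_used & ns$onset_s[i] <= det_t & det_t < ns$offset_s[i]),
    logical(1))) else 0L
  tn <- nrow(ns) - fp_ns_events
  # strays: unmatched swallow-decision detections outside every truth interval
  in_sw <- vapply(det_t, function(tt)
    any(sw$onset_s <= tt & tt < sw$offset_s), logical(1))
  stray <- sum(!det_used & !in_ns & !in_sw)
  dup <- sum(!det_used & in_sw)           # surplus detections in swallow truth
  confusion_table(tp = tp, fp = fp_ns_events + stray + dup, fn = fn, tn = tn)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums with midranks on ties. The p-value is exact
#' (full permutation null) when `n1 + n2 <= 12` and there are no ties,
#' otherwise a normal approximation with tie and continuity correction is
#' used.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @return a list of class `u_test_result`: `u_statistic`, `p_two_sided`,
#'   `n1`, `n2`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite values", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic),
                 p_two_sided = min(1, wt$p.value),
                 n1 = length(a), n2 = length(b),
                 method = if (exact) "exact" else "normal_approx"),
            class = "u_test_result")
}

#' @export
print.u_test_result <- function(x, ...) {
  cat(sprintf("<u_test> U=%g  p=%.4g  (n1=%d, n2=%d, %s)\n",
              x$u_statistic, x$p_two_sided, x$n1, x$n2, x$method))
  invisible(x)
}

#' Compare swallowing parameters between two groups
#'
#' One two-sided Mann-Whitney U test per swallowing-related parameter
#' (preparation duration, closure extent, maximum and speed of laryngeal
#' elevation), reported with group means and SDs.
#'
#' @param params_a,params_b feature data.frames from [extract_features()]
#'   (or any data.frames containing the four parameter columns).
#' @param parameters which columns to compare.
#' @return a data.frame with one row per parameter: `parameter`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `u_statistic`, `p_two_sided`, `method`.
#' @export
compare_groups <- function(params_a, params_b,
                           parameters = c("duration_preparation",
                                          "extent_laryngeal_closure",
                                          "max_laryngeal_elevation",
                                          "speed_laryngeal_elevation")) {
  if (!nrow(params_a) || !nrow(params_b))
    stop("both groups must be non-empty", call. = FALSE)
  rows <- lapply(parameters, function(p) {
    ut <- mann_whitney_u(params_a[[p]], params_b[[p]])
    data.frame(parameter = p,
               mean_a = mean(params_a[[p]]), sd_a = stats::sd(params_a[[p]]),
               mean_b = mean(params_b[[p]]), sd_b = stats::sd(params_b[[p]]),
               u_statistic = ut$u_statistic, p_two_sided = ut$p_two_sided,
               method = ut$method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
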