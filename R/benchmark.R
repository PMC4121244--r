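# Benchmark protocol: train the classifier on stage-1 candidates from a
# training split labeled against ground truth, detect on a held-out test
# split, and score event-wise.

#' Collect labeled training candidates from benchmark recordings
#'
#' Runs the stage-1 physiological filter on each recording and labels every
#' candidate by whether its valley minimum falls inside an annotated truth
#' swallow interval.
#'
#' @param benchmark list of recording bundles from [generate_benchmark()].
#' @param cfg a [default_pipeline_config()] list.
#' @return a list with `features` (data.frame) and `labels` (character).
#' @export
collect_training_candidates <- function(benchmark,
                                        cfg = default_pipeline_config()) {
  feats <- list(); labs <- list()
  for (b in benchmark) {
    cand <- stage1_candidates(b$recording, cfg)
    if (nrow(cand) == 0) next
    sw <- b$annotations[b$annotations$label == "swallow", , drop = FALSE]
    is_sw <- vapply(cand$t_bi_min, function(tt)
      any(sw$onset_s <= tt & tt < sw$offset_s), logical(1))
    feats[[length(feats) + 1L]] <- extract_features(cand)
    labs[[length(labs) + 1L]] <- ifelse(is_sw, "swallow", "nonswallow")
  }
  list(features = do.call(rbind, feats), labels = unlist(labs))
}

#' Stage-1 recall on benchmark recordings
#'
#' Fraction of annotated truth swallows for which the physiological
#' coincidence filter (EMG activity with a subsequent conforming BI valley)
#' produces at least one candidate whose `t_bi_min` falls inside the
#' swallow's annotation interval.
#'
#' @param benchmark list of recording bundles from [generate_benchmark()].
#' @param cfg a [default_pipeline_config()] list.
#' @return a list with `recall` (fraction in \[0, 1\]), `n_swallows` and
#'   `n_recalled`.
#' @export
stage1_recall <- function(benchmark, cfg = default_pipeline_config()) {
  n_sw <- 0L; n_hit <- 0L
  for (b in benchmark) {
    cand <- stage1_candidates(b$recording, cfg)
    sw <- b$annotations[b$annotations$label == "swallow", , drop = FALSE]
    n_sw <- n_sw + nrow(sw)
    if (nrow(sw) == 0) next
    hit <- vapply(seq_len(nrow(sw)), function(i)
      nrow(cand) > 0 && any(sw$onset_s[i] <= cand$t_bi_min &
                              cand$t_bi_min < sw$offset_s[i]), logical(1))
    n_hit <- n_hit + sum(hit)
  }
  list(recall = if (n_sw > 0) n_hit / n_sw else NA_real_,
       n_swallows = n_sw, n_recalled = n_hit)
}

#' Run the full train/test detection benchmark
#'
#' Generates `n_recordings` recordings for the given cohort regime, trains
#' the classifier on the first `n_train` (stage-1 candidates labeled against
#' ground truth), runs the two-stage detector on the remaining held-out
#' recordings, and scores the detections event-wise against the truth
#' annotations. Also reports stage-1 recall over all recordings.
#'
#' @param regime `"healthy"` or `"patient"`.
#' @param seed RNG seed for the benchmark generation.
#' @param n_recordings total recordings generated.
#' @param n_train recordings used for classifier training.
#' @param cfg a [default_pipeline_config()] list.
#' @param spec optional [cohort_spec()] override (defaults to the regime's
#'   standard spec).
#' @return a list with elements `confusion` ([confusion_table()] summed over
#'   the test split), `stage1` (list from [stage1_recall()] over all
#'   recordings), `model` (the trained classifier) and `regime`.
#' @export
run_detection_benchmark <- function(regime = c("healthy", "patient"),
                                    seed = 42, n_recordings = 40,
                                    n_train = 20,
                                    cfg = default_pipeline_config(),
                                    spec = NULL) {
  regime <- match.arg(regime)
  if (is.null(spec)) spec <- cohort_spec(regime)
  stopifnot(n_train >= 1, n_recordings > n_train)
  bench <- generate_benchmark(spec, n_recordings, seed = seed)
  train <- bench[seq_len(n_train)]
  test <- bench[(n_train + 1):n_recordings]

  tr <- collect_training_candidates(train, cfg)
  model <- train_classifier(tr$features, tr$labels,
                            cost = cfg$classifier$cost,
                            gamma = if (is.na(cfg$classifier$gamma)) NULL
                                    else cfg$classifier$gamma,
                            seed = seed)

  tp <- fp <- fn <- tn <- 0L
  for (b in test) {
    det <- detect_swallows(b$recording, model, cfg)
    ct <- match_events(det, b$annotations)
    tp <- tp + ct$tp; fp <- fp + ct$fp; fn <- fn + ct$fn; tn <- tn + ct$tn
  }
  list(confusion = confusion_table(tp, fp, fn, tn),
       stage1 = stage1_recall(bench, cfg),
       model = model, regime = regime)
}
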