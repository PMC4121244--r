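# Stage-2 discrimination: a soft-margin SVM with RBF kernel separates true
# swallows from movement artifacts (chewing, head movements) that survive
# the physiological coincidence filter. Feature z-scoring is fitted on the
# training data and stored with the model; the kernel width defaults to the
# median heuristic on the scaled training features.

#' Train the swallow/nonswallow classifier
#'
#' Z-scores the feature columns (means/scales stored in the model), sets the
#' RBF kernel width by the median heuristic on pairwise distances unless
#' `gamma` is supplied, and fits a soft-margin SVM. The score orientation is
#' fixed after training so that positive margins always mean "swallow".
#'
#' @param features data.frame of feature rows (see [extract_features()]).
#' @param labels character/factor vector, values `"swallow"` /
#'   `"nonswallow"`, one per row; at least 2 examples per class.
#' @param cost SVM soft-margin cost C.
#' @param gamma RBF kernel width; `NULL`/`NA` selects the median heuristic.
#' @param seed integer seed fixed before training (the fit itself is
#'   deterministic; the seed is stored as training metadata).
#' @return an object of class `swallow_classifier`.
#' @export
train_classifier <- function(features, labels, cost = 1, gamma = NULL,
                             seed = 1L) {
  labels <- as.character(labels)
  if (!all(labels %in% c("swallow", "nonswallow")))
    stop("labels must be 'swallow' or 'nonswallow'", call. = FALSE)
  if (length(labels) != nrow(features))
    stop("one label per feature row required", call. = FALSE)
  if (min(table(factor(labels, c("nonswallow", "swallow")))) < 2)
    stop("need at least 2 training examples per class", call. = FALSE)
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  mu <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  sc[sc <= .Machine$double.eps] <- 1
  xs <- scale(x, center = mu, scale = sc)

  if (is.null(gamma) || is.na(gamma)) {
    sub <- xs[seq_len(min(nrow(xs), 500L)), , drop = FALSE]
    d2 <- as.numeric(stats::dist(sub))^2
    med <- stats::median(d2[d2 > 0])
    if (!is.finite(med) || med <= 0) med <- ncol(xs)
    gamma <- 1 / (2 * med)
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  y <- factor(labels, levels = c("nonswallow", "swallow"))
  fit <- e1071::svm(x = xs, y = y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  flip <- if (mean(dv[y == "swallow"]) >= mean(dv[y == "nonswallow"])) 1 else -1

  structure(list(fit = fit, feature_names = colnames(x),
                 feature_means = mu, feature_scales = sc,
                 gamma = gamma, cost = cost, flip = flip, threshold = 0,
                 n_pos = sum(y == "swallow"), n_neg = sum(y == "nonswallow"),
                 seed = as.integer(seed), version = "1"),
            class = "swallow_classifier")
}

#' @export
print.swallow_classifier <- function(x, ...) {
  cat(sprintf(paste0("<swallow_classifier> RBF SVM, C=%g, gamma=%.4g, ",
                     "%d features, trained on %d swallows / %d nonswallows\n"),
              x$cost, x$gamma, length(x$feature_names), x$n_pos, x$n_neg))
  invisible(x)
}

#' Classify swallow candidates
#'
#' Applies the stored normalization and the trained SVM. The returned score
#' is the signed margin, oriented so positive means swallow; the decision is
#' `"swallow"` iff `score > threshold`.
#'
#' @param model a `swallow_classifier`.
#' @param features feature data.frame with exactly the columns the model
#'   was trained on.
#' @param threshold decision threshold on the signed margin; defaults to
#'   the model's stored threshold (0).
#' @return a data.frame with columns `score` and `decision`.
#' @export
classify_candidates <- function(model, features, threshold = NULL) {
  if (!inherits(model, "swallow_classifier"))
    stop("model must be a swallow_classifier", call. = FALSE)
  if (is.null(threshold)) threshold <- model$threshold
  if (!setequal(colnames(features), model$feature_names) ||
      ncol(features) != length(model$feature_names))
    stop("feature columns do not match the trained model", call. = FALSE)
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  xs <- scale(x, center = model$feature_means, scale = model$feature_scales)
  dv <- attr(stats::predict(model$fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  score <- model$flip * dv
  data.frame(score = score,
             decision = ifelse(score > threshold, "swallow", "nonswallow"))
}

#' Save / load a trained classifier
#'
#' The model file is a versioned, self-describing RDS container.
#' @param model a `swallow_classifier`.
#' @param path destination file.
#' @return `path` ([write_classifier()]) or the model ([read_classifier()]).
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "swallow_classifier"))
  saveRDS(list(format = "embidetect_classifier", version = model$version,
               model = model), path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "embidetect_classifier"))
    stop("not an embidetect classifier file", call. = FALSE)
  obj$model
}
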