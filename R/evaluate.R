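# Evaluation: confusion matrices, overall/per-class accuracy, repeated
# train/test trials, cross-subject transfer, and multi-session summaries.

#' Confusion matrix over the five postures
#'
#' `counts[t, p]` is the number of windows whose true label is `t` and
#' predicted label is `p`; rows are truth, columns predictions, both in
#' canonical order.
#'
#' @param truth,predicted Equal-length posture label vectors.
#' @return A `posture_confusion` matrix.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort(sprintf(
      "truth (%d) and predicted (%d) lengths differ.",
      length(truth), length(predicted)
    ))
  }
  cm <- table(truth = as_posture(truth), predicted = as_posture(predicted))
  structure(unclass(cm), class = c("posture_confusion", "matrix"))
}

#' @export
print.posture_confusion <- function(x, ...) {
  cat("Posture confusion matrix (rows = truth):\n")
  print(unclass(x))
  invisible(x)
}

#' Overall accuracy from a confusion matrix
#'
#' Correctly classified trials over total trials, each trial being one
#' window's feature vector.
#'
#' @param cm A `posture_confusion` (or square count matrix).
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort("Confusion matrix is empty.")
  sum(diag(cm)) / total
}

#' Per-class accuracy (recall) from a confusion matrix
#'
#' @param cm A `posture_confusion`.
#' @return Named numeric vector, `NA` for classes with no true instances.
#' @export
class_accuracy <- function(cm) {
  totals <- rowSums(cm)
  out <- diag(cm) / totals
  out[totals == 0] <- NA_real_
  out
}

# One seeded train/test run of the chosen algorithm on a dataset split.
.fit_and_score <- function(train, test, algorithm, seed, n_trees, C, gamma) {
  model <- switch(algorithm,
    rf = train_rf(train, n_trees = n_trees, seed = seed),
    svm = train_oaa_svm(train, C = C, gamma = gamma)
  )
  pred <- switch(algorithm,
    rf = predict_rf(model, test),
    svm = predict_oaa(model, test)
  )
  mean(pred == as_posture(test$posture))
}

#' Accuracy distribution over repeated train/test trials
#'
#' Re-splits, re-trains and re-tests the dataset `n_trials` times (seeded:
#' trial `k` uses `base_seed + k`), collecting the held-out accuracy of each
#' trial. A trial whose split leaves some class unrepresented is resampled
#' (counted, capped at 20 attempts). The summary reports the mean, the
#' 25th/75th percentiles, and Tukey outliers (beyond 1.5 IQR from the
#' quartiles).
#'
#' @param dataset A `posture_dataset`.
#' @param n_trials Number of trials (default 100).
#' @param algorithm `"rf"` or `"svm"`.
#' @param base_seed Integer base seed.
#' @param train_fraction Training fraction per trial (default 2/3).
#' @param n_trees Trees per forest when `algorithm = "rf"` (default 25).
#' @param C,gamma SVM hyperparameters when `algorithm = "svm"`.
#' @return An `accuracy_distribution` object.
#' @export
repeated_trials <- function(dataset, n_trials = 100, algorithm = c("rf", "svm"),
                            base_seed = 1, train_fraction = 2 / 3,
                            n_trees = 25, C = 1, gamma = NULL) {
  algorithm <- match.arg(algorithm)
  dataset <- as_tibble(dataset)
  classes <- unique(as.character(dataset$posture))
  acc <- numeric(n_trials)
  resampled <- 0L
  for (k in seq_len(n_trials)) {
    seed_k <- base_seed + k
    for (attempt in 0:20) {
      idx <- split_indices(nrow(dataset), train_fraction, seed_k + attempt * 100003L)
      tr <- dataset[idx$train, ]
      te <- dataset[idx$test, ]
      ok <- all(classes %in% as.character(tr$posture)) &&
        all(classes %in% as.character(te$posture))
      if (ok) break
      resampled <- resampled + 1L
      if (attempt == 20) abort("Trial split repeatedly missing a class; dataset too small.")
    }
    acc[k] <- .fit_and_score(tr, te, algorithm, seed_k, n_trees, C, gamma)
  }
  q <- quantile(acc, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  outliers <- acc[acc < q[1] - 1.5 * iqr | acc > q[2] + 1.5 * iqr]
  structure(
    list(
      accuracies = acc, algorithm = algorithm, n_trials = n_trials,
      base_seed = base_seed, resampled_splits = resampled,
      summary = list(
        mean = mean(acc), q25 = q[1], q75 = q[2], outliers = outliers
      )
    ),
    class = "accuracy_distribution"
  )
}

#' @export
print.accuracy_distribution <- function(x, ...) {
  cat(sprintf(
    "Accuracy over %d %s trials: mean %.4f, IQR [%.4f, %.4f], %d outlier(s)\n",
    x$n_trials, toupper(x$algorithm), x$summary$mean,
    x$summary$q25, x$summary$q75, length(x$summary$outliers)
  ))
  invisible(x)
}

#' Cross-subject transfer accuracy
#'
#' Trains on the source subject's dataset only and tests on the target
#' subject's dataset only, returning the overall accuracy — the protocol for
#' judging whether a posture model generalises across wearers.
#'
#' @param source,target `posture_dataset`s from two recording subjects.
#' @param algorithm `"rf"` or `"svm"`.
#' @param seed Seed for the forest (default 1).
#' @param n_trees,C,gamma Hyperparameters as in [repeated_trials()].
#' @return Overall accuracy fraction.
#' @export
cross_subject_eval <- function(source, target, algorithm = c("rf", "svm"),
                               seed = 1, n_trees = 25, C = 1, gamma = NULL) {
  algorithm <- match.arg(algorithm)
  src_classes <- unique(as.character(source$posture))
  tgt_classes <- unique(as.character(target$posture))
  if (length(intersect(src_classes, tgt_classes)) == 0) {
    abort("Source and target datasets share no posture classes.")
  }
  .fit_and_score(as_tibble(source), as_tibble(target), algorithm, seed, n_trees, C, gamma)
}

#' Multi-session accuracy summary
#'
#' @param session_accuracies Accuracy fractions, one per session.
#' @param threshold Count sessions with accuracy strictly above this
#'   (default 0.82).
#' @return One-row tibble with `mean` and `count_above`.
#' @export
#' @examples
#' session_summary(c(0.8244, 0.9464, 0.8405, 0.6005, 0.9571))
session_summary <- function(session_accuracies, threshold = 0.82) {
  if (length(session_accuracies) == 0) abort("No session accuracies supplied.")
  tibble(
    mean = mean(session_accuracies),
    count_above = sum(session_accuracies > threshold)
  )
}
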