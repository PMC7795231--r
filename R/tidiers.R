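# broom-style tidiers for the package's result objects.

#' Tidy a posture confusion matrix
#'
#' @param x A `posture_confusion`.
#' @param ... Unused.
#' @return Tibble with `truth, predicted, n`.
#' @method tidy posture_confusion
#' @export
tidy.posture_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "predicted", "n")
  tibble(
    truth = as_posture(df$truth),
    predicted = as_posture(df$predicted),
    n = as.integer(df$n)
  )
}

#' @rdname tidy.posture_confusion
#' @return `glance`: one-row tibble with `accuracy` and `n_trials`.
#' @method glance posture_confusion
#' @export
glance.posture_confusion <- function(x, ...) {
  tibble(accuracy = overall_accuracy(x), n_trials = sum(x))
}

#' Tidy an accuracy distribution
#'
#' @param x An `accuracy_distribution` from [repeated_trials()].
#' @param ... Unused.
#' @return Tibble with `trial, accuracy, outlier`.
#' @method tidy accuracy_distribution
#' @export
tidy.accuracy_distribution <- function(x, ...) {
  tibble(
    trial = seq_along(x$accuracies),
    accuracy = x$accuracies,
    outlier = x$accuracies %in% x$summary$outliers
  )
}

#' @rdname tidy.accuracy_distribution
#' @return `glance`: one-row tibble with mean, quartiles, outlier count and
#'   trial metadata.
#' @method glance accuracy_distribution
#' @export
glance.accuracy_distribution <- function(x, ...) {
  tibble(
    mean = x$summary$mean, q25 = x$summary$q25, q75 = x$summary$q75,
    n_outliers = length(x$summary$outliers),
    n_trials = x$n_trials, algorithm = x$algorithm
  )
}

#' Tidy an OAA SVM
#'
#' @param x An `oaa_svm`.
#' @param ... Unused.
#' @return Tibble with one row per binary model: `class, n_support, bias`.
#' @method tidy oaa_svm
#' @export
tidy.oaa_svm <- function(x, ...) {
  tibble(
    class = as_posture(x$classes),
    n_support = vapply(x$models, function(m) nrow(m$support_vectors), integer(1)),
    bias = vapply(x$models, function(m) m$bias, numeric(1))
  )
}

#' @rdname tidy.oaa_svm
#' @method glance oaa_svm
#' @export
glance.oaa_svm <- function(x, ...) {
  tibble(n_classes = length(x$classes), C = x$C, gamma = x$gamma)
}

#' Glance at a random forest posture model
#'
#' @param x A `posture_rf`.
#' @param ... Unused.
#' @return One-row tibble with `n_trees, seed, oob_error`.
#' @method glance posture_rf
#' @export
glance.posture_rf <- function(x, ...) {
  tibble(
    n_trees = x$n_trees, seed = x$seed,
    oob_error = x$forest$prediction.error
  )
}
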