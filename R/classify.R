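# Classifiers: one-against-all soft-margin SVM with an RBF kernel and
# literal vote tallying, and a random forest with tree-count selection.
# The binary dual problem is solved by libsvm's SMO (via e1071); everything
# around it — relabeling, kernel, decision rule, voting — is implemented
# here so the multiclass behaviour is exactly the documented one.

.feature_cols <- c("mu_x", "mu_y", "mu_z")

.feature_matrix <- function(data) {
  as.matrix(as_tibble(data)[.feature_cols])
}

#' One-against-all relabeling
#'
#' Maps a multiclass label vector to the binary +1/-1 coding used to train
#' the per-class SVM: +1 where the label equals the target class, -1
#' otherwise.
#'
#' @param labels Posture labels (character or factor).
#' @param target The class this binary model separates.
#' @return Integer vector of +1 / -1, same length as `labels`.
#' @export
#' @examples
#' oaa_relabel(c("Supine", "Prone", "Supine"), "Supine")
oaa_relabel <- function(labels, target) {
  ifelse(as.character(labels) == as.character(target), 1L, -1L)
}

#' RBF kernel
#'
#' `K(a, b) = exp(-gamma * ||a - b||^2)`, the radial basis similarity in
#' (0, 1]; equals 1 exactly when `a == b` or `gamma == 0`.
#'
#' @param a,b Numeric feature vectors of equal length.
#' @param gamma Non-negative kernel width parameter.
#' @return Similarity value in (0, 1].
#' @export
rbf_kernel <- function(a, b, gamma) {
  if (gamma < 0) abort("gamma must be non-negative.")
  exp(-gamma * sum((a - b)^2))
}

# Cross-kernel matrix K[i, j] = exp(-gamma ||X[i,] - Z[j,]||^2).
rbf_kernel_matrix <- function(X, Z, gamma) {
  if (gamma < 0) abort("gamma must be non-negative.")
  X <- as.matrix(X); Z <- as.matrix(Z)
  d2 <- outer(rowSums(X^2), rowSums(Z^2), `+`) - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Scale heuristic for gamma: 1 / (n_features * overall feature variance).
gamma_scale <- function(X) {
  v <- var(as.vector(as.matrix(X)))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

#' Train a binary soft-margin RBF SVM
#'
#' Solves the Lagrangian dual (box constraints `0 <= lambda_i <= C`,
#' equality `sum(lambda_i * y_i) = 0`) via sequential minimal optimization
#' and returns the support-vector expansion used by [svm_decision()]. The
#' decision sign is normalised so that positive values correspond to the +1
#' class.
#'
#' @param x Feature matrix or data frame with columns `mu_x, mu_y, mu_z`
#'   (or any numeric columns).
#' @param y Vector of +1 / -1, both classes present.
#' @param C Penalty constant (> 0), default 1.
#' @param gamma RBF parameter; default `1 / (n_features * var(features))`.
#' @param target_class Optional class name this model separates.
#' @param tolerance SMO termination tolerance (default 1e-6).
#' @return A `binary_svm` object: `support_vectors`, `dual_coefs`
#'   (lambda_i * y_i per support vector), `bias`, `gamma`, `C`,
#'   `target_class`.
#' @export
train_binary_svm <- function(x, y, C = 1, gamma = NULL, target_class = NA_character_,
                             tolerance = 1e-6) {
  X <- if (is.data.frame(x)) as.matrix(x) else x
  stopifnot(C > 0)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) abort("y must contain only +1 and -1.")
  if (length(unique(y)) < 2) {
    abort("Both classes must be present to train a binary SVM.")
  }
  if (is.null(gamma)) gamma <- gamma_scale(X)
  fit <- e1071::svm(
    x = X, y = factor(y, levels = c(1L, -1L)),
    type = "C-classification", kernel = "radial",
    cost = C, gamma = gamma, scale = FALSE, tolerance = tolerance
  )
  sv <- unname(as.matrix(fit$SV))
  coefs <- as.numeric(fit$coefs)
  bias <- -fit$rho
  # libsvm orients the sign toward the first label it encounters; normalise
  # so the decision value is positive on the +1 side.
  f_train <- as.numeric(rbf_kernel_matrix(sv, X, gamma) |> crossprod(coefs)) + bias
  if (sum(f_train * y) < 0) {
    coefs <- -coefs
    bias <- -bias
  }
  structure(
    list(
      support_vectors = sv, dual_coefs = coefs, bias = bias,
      gamma = gamma, C = C, target_class = target_class
    ),
    class = "binary_svm"
  )
}

#' Decision value of a binary SVM
#'
#' The raw kernel expansion `sum_i lambda_i y_i K(x_i, z) + b` before taking
#' the sign; see [svm_decision()].
#'
#' @param model A `binary_svm`.
#' @param z Feature matrix/data frame (rows are points) or a single numeric
#'   vector.
#' @return Numeric decision value(s).
#' @export
svm_decision_value <- function(model, z) {
  Z <- if (is.null(dim(z))) matrix(z, nrow = 1) else .as_probe_matrix(z)
  K <- rbf_kernel_matrix(model$support_vectors, Z, model$gamma)
  as.numeric(crossprod(K, model$dual_coefs)) + model$bias
}

.as_probe_matrix <- function(z) {
  if (is.data.frame(z)) {
    if (all(.feature_cols %in% names(z))) z <- z[.feature_cols]
    as.matrix(z)
  } else {
    as.matrix(z)
  }
}

#' Binary SVM class decision
#'
#' Sign of the kernel expansion plus bias; a decision value of exactly zero
#' is classified as +1 (deterministic convention for the measure-zero
#' boundary case).
#'
#' @inheritParams svm_decision_value
#' @return Integer vector of +1 / -1.
#' @export
svm_decision <- function(model, z) {
  f <- svm_decision_value(model, z)
  f[abs(f) < 1e-12] <- 0 # floating-point noise at an exact boundary
  ifelse(f >= 0, 1L, -1L)
}

#' Train a one-against-all SVM
#'
#' Builds one binary RBF SVM per class present in the training data, each on
#' the [oaa_relabel()] coding of the labels.
#'
#' @param dataset A `posture_dataset` (columns `mu_x, mu_y, mu_z, posture`).
#' @param C Penalty constant, default 1.
#' @param gamma RBF parameter; default scale heuristic (shared across the
#'   binary models).
#' @return An `oaa_svm` object: named list of `binary_svm` models (one per
#'   class, canonical order) plus hyperparameters.
#' @export
train_oaa_svm <- function(dataset, C = 1, gamma = NULL) {
  y <- as_posture(dataset$posture)
  classes <- .posture_levels[.posture_levels %in% unique(as.character(y))]
  if (length(classes) < 2) abort("Need at least 2 distinct classes to train an OAA SVM.")
  X <- .feature_matrix(dataset)
  if (is.null(gamma)) gamma <- gamma_scale(X)
  models <- lapply(classes, function(cl) {
    tryCatch(
      train_binary_svm(X, oaa_relabel(y, cl), C = C, gamma = gamma, target_class = cl),
      error = function(e) {
        abort(sprintf("Binary subproblem for class %s failed: %s", cl, conditionMessage(e)))
      }
    )
  })
  names(models) <- classes
  structure(
    list(models = models, classes = classes, C = C, gamma = gamma),
    class = "oaa_svm"
  )
}

#' @export
print.oaa_svm <- function(x, ...) {
  cat(sprintf(
    "One-against-all RBF SVM: %d classes (%s), C = %g, gamma = %g\n",
    length(x$classes), paste(x$classes, collapse = ", "), x$C, x$gamma
  ))
  invisible(x)
}

#' Predict postures with an OAA SVM
#'
#' Each binary model votes: a "+" outcome adds one vote to its own class; a
#' "-" outcome adds one vote to every other class (the literal one-against-
#' all voting rule). The class with the most votes wins; ties are broken
#' toward the earliest class in the canonical order, with a warning.
#'
#' @param model An `oaa_svm`.
#' @param newdata Data frame with columns `mu_x, mu_y, mu_z`, or a numeric
#'   matrix / single feature vector.
#' @param method `"vote"` (default, the literal voting rule) or `"margin"`
#'   (argmax of the raw decision values).
#' @return Posture factor, one prediction per row.
#' @export
predict_oaa <- function(model, newdata, method = c("vote", "margin")) {
  method <- match.arg(method)
  Z <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else .as_probe_matrix(newdata)
  k <- length(model$classes)
  dec <- vapply(model$models, function(m) svm_decision_value(m, Z), numeric(nrow(Z)))
  dec <- matrix(dec, nrow = nrow(Z), ncol = k)
  if (method == "margin") {
    win <- max.col(dec, ties.method = "first")
    return(as_posture(model$classes[win]))
  }
  signs <- dec >= 0
  # votes[z, h] = own "+" vote + one vote from every other model voting "-"
  votes <- matrix(0L, nrow = nrow(Z), ncol = k)
  for (h in seq_len(k)) {
    votes[, h] <- votes[, h] + as.integer(signs[, h])
    votes[, -h] <- votes[, -h] + as.integer(!signs[, h])
  }
  ties <- apply(votes, 1, function(v) sum(v == max(v)) > 1)
  if (any(ties)) {
    warn(sprintf(
      "OAA vote tie in %d case(s); broken toward the earliest class in canonical order.",
      sum(ties)
    ))
  }
  win <- max.col(votes, ties.method = "first")
  as_posture(model$classes[win])
}

#' @rdname predict_oaa
#' @param object,... S3 method arguments (`...` passed to [predict_oaa()]).
#' @export
predict.oaa_svm <- function(object, newdata, ...) predict_oaa(object, newdata, ...)

#' Train a random forest posture model
#'
#' Bootstrap-sampled, random-feature-split tree ensemble; prediction is a
#' majority vote over trees ([predict_rf()]). The tree learner is `ranger`;
#' the vote tally and its fixed-order tie-break are implemented here.
#'
#' @param dataset A `posture_dataset`.
#' @param n_trees Number of trees (>= 1).
#' @param seed Integer seed; the same seed and data give identical
#'   predictions.
#' @param mtry Features tried per split (default 1 of the 3 axis means).
#' @return A `posture_rf` object.
#' @export
train_rf <- function(dataset, n_trees, seed, mtry = 1) {
  stopifnot(n_trees >= 1)
  if (nrow(dataset) == 0) abort("Cannot train a random forest on an empty dataset.")
  df <- as_tibble(dataset)[c(.feature_cols, "posture")]
  df$posture <- as_posture(df$posture)
  fit <- suppressWarnings(ranger::ranger(
    posture ~ mu_x + mu_y + mu_z,
    data = df, num.trees = n_trees, mtry = mtry,
    seed = seed, num.threads = 1
  ))
  structure(
    list(forest = fit, n_trees = as.integer(n_trees), seed = as.integer(seed)),
    class = "posture_rf"
  )
}

#' Predict postures with a random forest
#'
#' Majority vote over the individual trees' predictions; ties are broken
#' toward the earliest class in the canonical order (a message reports how
#' many).
#'
#' @param model A `posture_rf`.
#' @param newdata Data frame with columns `mu_x, mu_y, mu_z`.
#' @return Posture factor, one prediction per row.
#' @export
predict_rf <- function(model, newdata) {
  df <- as_tibble(newdata)
  pa <- predict(model$forest, data = df[.feature_cols],
                predict.all = TRUE, num.threads = 1)$predictions
  pa <- matrix(pa, nrow = nrow(df))
  lev <- model$forest$forest$levels
  # tally votes per row in canonical order; max.col("first") = earliest wins
  votes <- vapply(seq_along(.posture_levels), function(j) {
    code <- match(.posture_levels[j], lev)
    rowSums(pa == code)
  }, numeric(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  ties <- apply(votes, 1, function(v) sum(v == max(v)) > 1)
  if (any(ties)) {
    inform(sprintf(
      "Random-forest vote tie in %d case(s); broken toward the earliest class.",
      sum(ties)
    ))
  }
  as_posture(.posture_levels[max.col(votes, ties.method = "first")])
}

#' @rdname predict_rf
#' @param object,... S3 method arguments (ignored extras).
#' @export
predict.posture_rf <- function(object, newdata, ...) predict_rf(object, newdata)

#' Seeded train/test row split
#'
#' Draws a reproducible random split of `1:n` into training and test index
#' vectors, both returned sorted. The same `(n, train_fraction, seed)` always
#' yields the same split.
#'
#' @param n Number of rows to split.
#' @param train_fraction Fraction assigned to training (rounded to a count).
#' @param seed Integer seed for the draw.
#' @return A list with sorted integer vectors `train` and `test`.
#' @export
split_indices <- function(n, train_fraction, seed) {
  withr::with_seed(seed, {
    n_train <- round(train_fraction * n)
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Select the random-forest tree count
#'
#' Splits the dataset once (seeded; default two thirds training, one third
#' validation), trains a forest for every tree count from 1 to `max_trees`,
#' and returns the count with the highest validation accuracy (ties go to
#' the smallest count). The per-candidate validation accuracies are attached
#' as the `"validation_accuracy"` attribute.
#'
#' @param dataset A `posture_dataset`.
#' @param max_trees Largest candidate tree count (default 50).
#' @param train_fraction Fraction of rows used for training (default 2/3).
#' @param seed Integer seed for the split and the forests.
#' @return Integer tree count in `[1, max_trees]`.
#' @export
select_tree_count <- function(dataset, max_trees = 50, train_fraction = 2 / 3, seed = 1) {
  dataset <- as_tibble(dataset)
  idx <- split_indices(nrow(dataset), train_fraction, seed)
  train <- dataset[idx$train, ]
  val <- dataset[idx$test, ]
  classes <- unique(as.character(dataset$posture))
  miss_val <- setdiff(classes, as.character(val$posture))
  miss_tr <- setdiff(classes, as.character(train$posture))
  if (length(miss_val) > 0 || length(miss_tr) > 0) {
    abort(sprintf(
      "Split leaves class(es) unrepresented (%s); use a larger dataset or another seed.",
      paste(union(miss_val, miss_tr), collapse = ", ")
    ))
  }
  acc <- vapply(seq_len(max_trees), function(nt) {
    m <- train_rf(train, n_trees = nt, seed = seed)
    mean(predict_rf(m, val) == val$posture)
  }, numeric(1))
  best <- which.max(acc) # which.max returns the first (smallest) maximiser
  structure(as.integer(best), validation_accuracy = acc)
}

#' Save / load a posture model archive
#'
#' Persists a trained model (`oaa_svm` or `posture_rf`) together with a
#' format version and the canonical class order; loading and predicting
#' reproduces the in-memory predictions exactly.
#'
#' @param model The trained model.
#' @param path Archive path (RDS).
#' @return `path` invisibly (`write_model`); the model (`read_model`).
#' @export
write_model <- function(model, path) {
  saveRDS(list(
    format_version = 1L,
    class_order = .posture_levels,
    algorithm = if (inherits(model, "oaa_svm")) "svm" else "rf",
    model = model
  ), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$format_version, 1L)) {
    abort(sprintf("Unsupported model archive version: %s", arch$format_version))
  }
  arch$model
}
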