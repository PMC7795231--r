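test_that("oaa_relabel produces the +1/-1 coding", {
  expect_equal(oaa_relabel(c("Supine", "Prone", "Supine"), "Supine"), c(1L, -1L, 1L))
  expect_equal(oaa_relabel(c("Supine", "Prone"), "Stand"), c(-1L, -1L))
  labs <- c("Supine", "Prone", "Prone", "Supine")
  expect_equal(oaa_relabel(labs, "Supine"), -oaa_relabel(labs, "Prone"))
})

test_that("rbf_kernel matches its closed form and edge cases", {
  a <- c(0.3, -0.2, 0.9)
  expect_equal(rbf_kernel(a, a, gamma = 2.5), 1)
  expect_equal(rbf_kernel(a, c(1, 1, 1), gamma = 0), 1)
  expect_equal(rbf_kernel(c(0, 0, 0), c(1, 0, 0), gamma = 1), exp(-1))
  expect_equal(rbf_kernel(a, c(0, 0, 0), 0.7), rbf_kernel(c(0, 0, 0), a, 0.7))
  expect_error(rbf_kernel(a, a, gamma = -1), "non-negative")
})

test_that("RBF kernel matrices are symmetric positive semidefinite", {
  set.seed(14)
  for (rep in 1:10) {
    X <- matrix(rnorm(3 * sample(3:8, 1)), ncol = 3)
    K <- somnipose:::rbf_kernel_matrix(X, X, gamma = runif(1, 0.1, 3))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("two symmetric points give a zero decision value at the midpoint", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0))
  m <- train_binary_svm(X, c(-1L, 1L), C = 1000, gamma = 1)
  expect_lt(abs(svm_decision_value(m, c(0.5, 0, 0))), 1e-9)
  # sign(0) convention: the boundary is classified +1
  expect_equal(svm_decision(m, c(0.5, 0, 0)), 1L)
  expect_equal(svm_decision(m, c(1, 0, 0)), 1L)
  expect_equal(svm_decision(m, c(0, 0, 0)), -1L)
  # the analytic dual of this symmetric pair has lambda1 = lambda2
  expect_equal(m$dual_coefs[1], -m$dual_coefs[2], tolerance = 1e-8)
})

test_that("trained binary models satisfy dual feasibility and separate separable data", {
  set.seed(41)
  for (rep in 1:5) {
    X <- rbind(
      matrix(rnorm(30, mean = 0, sd = 0.3), ncol = 3),
      matrix(rnorm(30, mean = 3, sd = 0.3), ncol = 3)
    )
    y <- rep(c(-1L, 1L), each = 10)
    C <- 100
    m <- train_binary_svm(X, y, C = C, gamma = 0.5)
    expect_true(all(abs(m$dual_coefs) <= C + 1e-6))
    expect_lt(abs(sum(m$dual_coefs)), 1e-6)
    expect_equal(svm_decision(m, X), y)
  }
})

test_that("duplicating every training point leaves the decision function unchanged", {
  set.seed(42)
  X <- matrix(rnorm(24), ncol = 3)
  y <- rep(c(-1L, 1L), each = 4)
  m1 <- train_binary_svm(X, y, C = 10, gamma = 1)
  m2 <- train_binary_svm(rbind(X, X), c(y, y), C = 10, gamma = 1)
  probes <- matrix(rnorm(60), ncol = 3)
  expect_equal(svm_decision_value(m1, probes), svm_decision_value(m2, probes),
               tolerance = 1e-3)
})

test_that("single-class input is rejected", {
  X <- matrix(rnorm(12), ncol = 3)
  expect_error(train_binary_svm(X, rep(1L, 4)), "Both classes")
  ds <- tibble::tibble(mu_x = rnorm(5), mu_y = rnorm(5), mu_z = rnorm(5),
                       posture = as_posture(rep("Prone", 5)))
  expect_error(train_oaa_svm(ds), "2 distinct classes")
})

test_that("train_oaa_svm builds one binary model per class", {
  ds <- profile_dataset("separable", seed = 7)
  lying <- ds[ds$posture != "Stand", ]
  m4 <- train_oaa_svm(lying)
  expect_length(m4$models, 4)
  expect_setequal(m4$classes, c("Supine", "RightLateral", "LeftLateral", "Prone"))

  two <- ds[ds$posture %in% c("Supine", "Prone"), ]
  m2 <- train_oaa_svm(two)
  expect_length(m2$models, 2)
  # two-class relabelings are mirrored, so the binary decisions oppose
  probes <- two[seq(1, nrow(two), by = 10), ]
  d_sup <- svm_decision_value(m2$models$Supine, probes)
  d_pro <- svm_decision_value(m2$models$Prone, probes)
  expect_true(all(sign(d_sup) == -sign(d_pro)))
})

test_that("per-class decision functions ignore training-row order", {
  ds <- profile_dataset("separable", seed = 8)[, ]
  shuffled <- ds[sample.int(nrow(ds)), ]
  m1 <- train_oaa_svm(ds, C = 1, gamma = 1)
  m2 <- train_oaa_svm(shuffled, C = 1, gamma = 1)
  probes <- ds[seq(1, nrow(ds), by = 25), ]
  for (cl in m1$classes) {
    expect_equal(svm_decision_value(m1$models[[cl]], probes),
                 svm_decision_value(m2$models[[cl]], probes),
                 tolerance = 1e-4)
  }
})

test_that("the literal OAA voting rule matches an independent tally for k = 4", {
  classes <- c("Supine", "RightLateral", "LeftLateral", "Prone")
  # constant-sign binary models: decision value is just the bias
  const_model <- function(sign, cl) {
    structure(list(
      support_vectors = matrix(0, 1, 3), dual_coefs = 0,
      bias = sign, gamma = 1, C = 1, target_class = cl
    ), class = "binary_svm")
  }
  z <- c(0, 0, 1)
  for (pattern in 0:15) {
    signs <- ifelse(bitwAnd(pattern, 2^(0:3)) > 0, 1, -1)
    oaa <- structure(
      list(models = setNames(purrr::map2(signs, classes, const_model), classes),
           classes = classes, C = 1, gamma = 1),
      class = "oaa_svm"
    )
    # independent tally of the literal rule
    votes <- setNames(rep(0L, 4), classes)
    for (h in 1:4) {
      if (signs[h] > 0) votes[h] <- votes[h] + 1L
      else votes[-h] <- votes[-h] + 1L
    }
    expected <- classes[which.max(votes)] # which.max = earliest on ties
    got <- suppressWarnings(as.character(predict_oaa(oaa, z)))
    expect_equal(got, expected, info = paste("pattern", pattern))
    if (sum(signs > 0) == 1) {
      # a single "+" always elects that model's class
      expect_equal(got, classes[signs > 0])
    }
  }
  # all-minus pattern: every class gets k-1 votes; tie -> earliest class
  all_minus <- structure(
    list(models = setNames(purrr::map2(rep(-1, 4), classes, const_model), classes),
         classes = classes, C = 1, gamma = 1),
    class = "oaa_svm"
  )
  expect_warning(tie <- predict_oaa(all_minus, z), "tie")
  expect_equal(as.character(tie), "Supine")
})

test_that("OAA predictions match nearest-class-mean on well-separated data", {
  ds <- profile_dataset("separable", seed = 12)
  lying <- ds[ds$posture != "Stand", ]
  idx <- somnipose:::split_indices(nrow(lying), 2 / 3, 12)
  train <- lying[idx$train, ]
  test <- lying[idx$test, ]
  model <- train_oaa_svm(train)
  pred <- predict_oaa(model, test)

  centroids <- train |>
    dplyr::group_by(posture) |>
    dplyr::summarise(dplyr::across(c(mu_x, mu_y, mu_z), mean), .groups = "drop")
  nearest <- apply(as.matrix(test[, c("mu_x", "mu_y", "mu_z")]), 1, function(z) {
    d <- rowSums((as.matrix(centroids[, -1]) - matrix(z, nrow(centroids), 3, byrow = TRUE))^2)
    as.character(centroids$posture[which.min(d)])
  })
  expect_gte(mean(as.character(pred) == nearest), 0.99)
})

test_that("random forests are seed-reproducible and single-tree consistent", {
  ds <- profile_dataset("separable", seed = 19)
  idx <- somnipose:::split_indices(nrow(ds), 2 / 3, 19)
  train <- ds[idx$train, ]
  probe <- ds[idx$test, ]
  m1 <- train_rf(train, n_trees = 15, seed = 99)
  m2 <- train_rf(train, n_trees = 15, seed = 99)
  expect_equal(predict_rf(m1, probe), predict_rf(m2, probe))

  single <- train_rf(train, n_trees = 1, seed = 99)
  pa <- predict(single$forest, data = probe[, c("mu_x", "mu_y", "mu_z")],
                predict.all = TRUE, num.threads = 1)$predictions
  lone_tree <- as_posture(single$forest$forest$levels[as.vector(pa)])
  expect_equal(predict_rf(single, probe), lone_tree)

  expect_error(train_rf(ds[0, ], n_trees = 5, seed = 1), "empty")
})

test_that("noiseless separable data is classified perfectly by the forest", {
  cfg <- simulation_config(
    tibble::tibble(posture = c("Stand", "Supine", "RightLateral", "LeftLateral", "Prone"),
                   dwell_s = c(10, 20, 20, 20, 20)),
    noise_sd_g = 0, glitch_rate = 0, wrist_orientation_sd = 0, seed = 23
  )
  ds <- session_dataset(simulate_session(cfg))
  idx <- somnipose:::split_indices(nrow(ds), 2 / 3, 23)
  m <- train_rf(ds[idx$train, ], n_trees = 10, seed = 23)
  expect_equal(mean(predict_rf(m, ds[idx$test, ]) == ds$posture[idx$test]), 1.0)
})

test_that("select_tree_count returns an argmax count within bounds", {
  ds <- profile_dataset("confusable", seed = 31)
  expect_equal(as.integer(select_tree_count(ds, max_trees = 1, seed = 31)), 1L)

  best <- select_tree_count(ds, max_trees = 12, seed = 31)
  acc <- attr(best, "validation_accuracy")
  expect_true(best >= 1 && best <= 12)
  expect_equal(acc[as.integer(best)], max(acc))
  # ties resolve to the smallest candidate
  expect_true(all(acc[seq_len(as.integer(best) - 1)] < max(acc)))

  # a one-row validation split can never contain two classes
  tiny <- tibble::tibble(
    frame_index = 1:3, mu_x = c(0, 0, 1), mu_y = 0, mu_z = c(1, 1, 0),
    posture = as_posture(c("Supine", "Supine", "Prone"))
  )
  expect_error(select_tree_count(tiny, max_trees = 3, seed = 1), "unrepresented")
})

test_that("model archives round-trip predictions exactly", {
  ds <- profile_dataset("separable", seed = 37)
  probe <- ds[seq(1, nrow(ds), by = 7), ]
  for (model in list(train_oaa_svm(ds), train_rf(ds, n_trees = 9, seed = 37))) {
    path <- withr::local_tempfile(fileext = ".rds")
    write_model(model, path)
    loaded <- read_model(path)
    p1 <- if (inherits(model, "oaa_svm")) predict_oaa(model, probe) else predict_rf(model, probe)
    p2 <- if (inherits(loaded, "oaa_svm")) predict_oaa(loaded, probe) else predict_rf(loaded, probe)
    expect_identical(p1, p2)
  }
})

test_that("both classifiers recover well-separated synthetic postures", {
  for (seed in c(61, 62)) {
    ds <- profile_dataset("separable", seed = seed)
    expect_gte(holdout_accuracy(ds, "svm", seed), 0.95)
    expect_gte(holdout_accuracy(ds, "rf", seed), 0.95)
  }
})
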