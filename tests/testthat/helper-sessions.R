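# Shared fixtures: small streams and end-to-end simulated datasets.

make_stream <- function(ts, ax, ay, az, site = "chest") {
  sensor_stream(
    tibble::tibble(timestamp_ms = ts, ax = ax, ay = ay, az = az),
    site = site
  )
}

# A constant-orientation stream: n samples of one acceleration triple.
constant_stream <- function(acc, n = 60, rate = 60, site = "chest") {
  ts <- as.integer(floor((seq_len(n) - 1) * 1000 / rate))
  make_stream(ts, rep(acc[1], n), rep(acc[2], n), rep(acc[3], n), site = site)
}

# Full pipeline on a simulated session: chest labels joined to wrist features.
session_dataset <- function(session, windowsize_ms = 1000, calibration_s = 5) {
  ref <- session$chest[session$chest$timestamp_ms < calibration_s * 1000, ]
  rotation <- compute_calibration(ref)
  labels <- suppressMessages(label_stream(session$chest, rotation,
                                          window_ms = windowsize_ms))
  features <- suppressMessages(frame_means(session$wrist,
                                           windowsize_ms = windowsize_ms))
  suppressMessages(build_dataset(features, labels))
}

# Seeded profile dataset in one call.
profile_dataset <- function(profile, seed) {
  session_dataset(suppressMessages(simulate_session(default_config(profile, seed = seed))))
}

holdout_accuracy <- function(dataset, algorithm, seed, n_trees = 25) {
  idx <- somnipose:::split_indices(nrow(dataset), 2 / 3, seed)
  train <- dataset[idx$train, ]
  test <- dataset[idx$test, ]
  pred <- if (algorithm == "svm") {
    predict_oaa(train_oaa_svm(train), test)
  } else {
    predict_rf(train_rf(train, n_trees = n_trees, seed = seed), test)
  }
  mean(pred == test$posture)
}
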