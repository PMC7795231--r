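# Wrist-sensor pipeline: frame segmentation, per-frame axis means, and the
# join with chest-derived labels into the training design matrix.

#' Segment a stream into fixed-duration frames
#'
#' Frames are half-open intervals `windowsize * (i - 1) <= t < windowsize * i`
#' with 1-based index `i`; together they partition the records. Frames with
#' no records are omitted (a gap message is emitted).
#'
#' @param stream A `sensor_stream`.
#' @param windowsize_ms Frame length in milliseconds (default 1000).
#' @return The stream's records as a tibble with an added `frame_index`
#'   column.
#' @export
segment_frames <- function(stream, windowsize_ms = 1000) {
  stopifnot(windowsize_ms > 0)
  out <- as_tibble(stream) |>
    mutate(frame_index = as.integer(.data$timestamp_ms %/% as.integer(windowsize_ms)) + 1L) |>
    relocate("frame_index")
  if (nrow(out) > 0) {
    present <- unique(out$frame_index)
    gaps <- setdiff(seq_len(max(present)), present)
    if (length(gaps) > 0) {
      inform(sprintf("segment_frames: %d empty frame(s) omitted.", length(gaps)))
    }
  }
  out
}

#' Mean feature vector of one frame
#'
#' @param frame Data frame of records (columns `ax, ay, az`) belonging to a
#'   single frame.
#' @return One-row tibble with `mu_x, mu_y, mu_z`.
#' @export
frame_mean <- function(frame) {
  if (nrow(frame) == 0) abort("Cannot take the mean of an empty frame.")
  tibble(mu_x = mean(frame$ax), mu_y = mean(frame$ay), mu_z = mean(frame$az))
}

#' Per-frame mean features for a whole stream
#'
#' Convenience composition of [segment_frames()] and [frame_mean()]: the
#' feature matrix whose rows are the per-axis means of each non-empty frame.
#'
#' @param stream A `sensor_stream`.
#' @param windowsize_ms Frame length in milliseconds (default 1000).
#' @return Tibble with `frame_index, mu_x, mu_y, mu_z, n`.
#' @export
frame_means <- function(stream, windowsize_ms = 1000) {
  segment_frames(stream, windowsize_ms) |>
    group_by(.data$frame_index) |>
    summarise(
      mu_x = mean(.data$ax), mu_y = mean(.data$ay), mu_z = mean(.data$az),
      n = dplyr::n(), .groups = "drop"
    ) |>
    arrange(.data$frame_index)
}

#' Join wrist features with chest labels into a training dataset
#'
#' Both sensors stream to the same session clock, so wrist frames and chest
#' windows computed with the same window size share indices. Rows are joined
#' on index; rows present on only one side are dropped and counted.
#'
#' @param features Tibble from [frame_means()] (wrist side).
#' @param labels Tibble with `window_index, posture` from [label_stream()]
#'   (chest side).
#' @param keep_stand Keep `Stand` windows as a fifth class (default `TRUE`);
#'   set `FALSE` for a sleep-only model.
#' @return A `posture_dataset` tibble with
#'   `frame_index, mu_x, mu_y, mu_z, posture`.
#' @export
build_dataset <- function(features, labels, keep_stand = TRUE) {
  lab <- tibble(frame_index = labels$window_index, posture = as_posture(labels$posture))
  joined <- inner_join(
    features[c("frame_index", "mu_x", "mu_y", "mu_z")], lab,
    by = "frame_index"
  ) |> arrange(.data$frame_index)
  dropped_feat <- nrow(features) - nrow(joined)
  dropped_lab <- nrow(lab) - nrow(joined)
  if (dropped_feat > 0 || dropped_lab > 0) {
    inform(sprintf(
      "build_dataset: dropped %d unlabeled frame(s) and %d label(s) without features.",
      dropped_feat, dropped_lab
    ))
  }
  if (!keep_stand) joined <- filter(joined, .data$posture != "Stand")
  if (nrow(joined) == 0) abort("No overlapping windows between features and labels.")
  class(joined) <- c("posture_dataset", class(joined))
  joined
}

#' Write a labeled dataset to CSV
#' @param dataset A `posture_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  readr::write_csv(
    mutate(as_tibble(dataset), posture = as.character(.data$posture)),
    path
  )
  invisible(path)
}

#' Read a labeled dataset from CSV
#' @param path Path to a CSV with header `frame_index,mu_x,mu_y,mu_z,posture`.
#' @return A `posture_dataset` tibble.
#' @export
read_dataset <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    frame_index = readr::col_integer(),
    mu_x = readr::col_double(), mu_y = readr::col_double(),
    mu_z = readr::col_double(), posture = readr::col_character()
  ))
  df$posture <- as_posture(df$posture)
  class(df) <- c("posture_dataset", class(df))
  df
}
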