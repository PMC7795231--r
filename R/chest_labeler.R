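# Chest-sensor pipeline: calibration rotation -> variance-threshold noise
# removal -> one-second window means -> dominant-axis posture rules.

#' Compute the chest calibration rotation
#'
#' While the wearer stands (or sits) straight, gravity should load the
#' sensor's X axis. The calibration angle is the two-argument arctangent of
#' the reference stream's mean Y and mean X: theta = atan2(mean(ay),
#' mean(ax)). Applying the resulting planar rotation to the reference mean
#' yields (sqrt(mean_x^2 + mean_y^2), 0) — gravity entirely on X'.
#'
#' @param reference A `sensor_stream` recorded while the wearer is upright.
#' @return A `calibration_rotation` object with field `theta_rad` in
#'   (-pi, pi].
#' @export
compute_calibration <- function(reference) {
  if (nrow(reference) == 0) abort("Calibration reference stream is empty.")
  mx <- mean(reference$ax)
  my <- mean(reference$ay)
  if (sqrt(mx^2 + my^2) < 1e-12) {
    abort("Degenerate calibration reference: mean X and Y acceleration are both zero (sensor flat).")
  }
  structure(list(theta_rad = atan2(my, mx)), class = "calibration_rotation")
}

#' @export
print.calibration_rotation <- function(x, ...) {
  cat(sprintf("Calibration rotation: theta = %.6f rad (%.2f deg)\n",
              x$theta_rad, x$theta_rad * 180 / pi))
  invisible(x)
}

#' Apply a calibration rotation to a stream
#'
#' Rotates each record's (x, y) pair by `-theta` so the upright gravity
#' direction maps onto X': `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`. Z and timestamps are untouched; the
#' planar rotation preserves every record's XY norm.
#'
#' @param rotation A `calibration_rotation` from [compute_calibration()].
#' @param stream A `sensor_stream`.
#' @return The calibrated `sensor_stream`.
#' @export
apply_calibration <- function(rotation, stream) {
  stopifnot(inherits(rotation, "calibration_rotation"))
  ct <- cos(rotation$theta_rad)
  st <- sin(rotation$theta_rad)
  x <- stream$ax
  y <- stream$ay
  stream$ax <- x * ct + y * st
  stream$ay <- -x * st + y * ct
  stream
}

#' Remove low-magnitude glitch samples
#'
#' The sensors occasionally emit spurious records with extremely small
#' values. Within each non-overlapping window the sample variance of the
#' vector magnitudes is computed and used as a threshold: records whose
#' magnitude falls below it are dropped. A window of identical samples has
#' zero variance, so nothing is ever removed from it.
#'
#' @param stream A `sensor_stream`.
#' @param window_ms Window length in milliseconds (default 1000).
#' @param stat Statistic the threshold is applied to: `"magnitude"`
#'   (default; vector norm of each record) or `"per_axis"` (a record is
#'   dropped when every axis' absolute value falls below that axis' window
#'   variance).
#' @return The cleaned `sensor_stream`; may be empty.
#' @export
remove_noise <- function(stream, window_ms = 1000,
                         stat = c("magnitude", "per_axis")) {
  stat <- match.arg(stat)
  stopifnot(window_ms > 0)
  if (nrow(stream) == 0) return(stream)
  win <- stream$timestamp_ms %/% as.integer(window_ms)
  keep <- if (stat == "magnitude") {
    mag <- sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
    unsplit(lapply(split(mag, win), function(m) {
      v <- if (length(m) > 1) var(m) else 0
      m >= v
    }), win)
  } else {
    idx <- split(seq_len(nrow(stream)), win)
    k <- logical(nrow(stream))
    for (ii in idx) {
      vx <- if (length(ii) > 1) var(stream$ax[ii]) else 0
      vy <- if (length(ii) > 1) var(stream$ay[ii]) else 0
      vz <- if (length(ii) > 1) var(stream$az[ii]) else 0
      k[ii] <- !(abs(stream$ax[ii]) < vx &
                   abs(stream$ay[ii]) < vy &
                   abs(stream$az[ii]) < vz)
    }
    k
  }
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("remove_noise: dropped %d low-magnitude record(s).", dropped))
  }
  out <- stream[keep, , drop = FALSE]
  attributes(out)[c("site", "nominal_rate_hz")] <-
    attributes(stream)[c("site", "nominal_rate_hz")]
  class(out) <- class(stream)
  out
}

#' Per-window axis means
#'
#' Segments the stream into non-overlapping half-open windows
#' `[k * window_ms, (k+1) * window_ms)` (1-based `window_index`) and returns
#' the per-axis arithmetic means. Windows containing no records are omitted.
#'
#' @param stream A `sensor_stream`.
#' @param window_ms Window length in milliseconds (default 1000, i.e. one
#'   second at the nominal 60 Hz).
#' @return Tibble with `window_index, mu_x, mu_y, mu_z, n`.
#' @export
window_means <- function(stream, window_ms = 1000) {
  stopifnot(window_ms > 0)
  stream |>
    as_tibble() |>
    mutate(window_index = as.integer(.data$timestamp_ms %/% as.integer(window_ms)) + 1L) |>
    group_by(.data$window_index) |>
    summarise(
      mu_x = mean(.data$ax), mu_y = mean(.data$ay), mu_z = mean(.data$az),
      n = dplyr::n(), .groups = "drop"
    ) |>
    arrange(.data$window_index)
}

#' Posture from calibrated window means
#'
#' The dominant axis is the one with the largest absolute mean. X dominant
#' means the wearer is upright (`Stand`); otherwise the sign of the dominant
#' lying axis decides: Y' positive is `LeftLateral`, Y' negative
#' `RightLateral`, Z positive `Supine`, Z negative `Prone`. Exact dominance
#' ties (measure zero on real data) are broken by the fixed priority
#' X > Y' > Z, with a warning.
#'
#' @param features Data frame with columns `mu_x, mu_y, mu_z` (calibrated),
#'   one row per window.
#' @return Posture factor, one element per row.
#' @export
#' @examples
#' label_posture(data.frame(mu_x = 0.1, mu_y = 0.05, mu_z = 0.9)) # Supine
label_posture <- function(features) {
  a <- abs(cbind(features$mu_x, features$mu_y, features$mu_z))
  if (nrow(a) == 0) return(as_posture(character()))
  ties <- apply(a, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) {
    warn(sprintf(
      "Dominance tie in %d window(s); broken by priority X > Y' > Z.",
      sum(ties)
    ))
  }
  dom <- max.col(a, ties.method = "first")
  lab <- character(nrow(a))
  lab[dom == 1] <- "Stand"
  lab[dom == 2] <- ifelse(features$mu_y[dom == 2] >= 0, "LeftLateral", "RightLateral")
  lab[dom == 3] <- ifelse(features$mu_z[dom == 3] >= 0, "Supine", "Prone")
  as_posture(lab)
}

#' Chest stream to per-window posture labels
#'
#' Full chest pipeline: [apply_calibration()] with the supplied rotation,
#' [remove_noise()], [window_means()], then [label_posture()] on each
#' surviving window.
#'
#' @param stream A chest `sensor_stream`.
#' @param rotation A `calibration_rotation`.
#' @param window_ms Window length in milliseconds (default 1000).
#' @param noise_stat Passed to [remove_noise()] as `stat`.
#' @return Tibble with `window_index, posture`.
#' @export
label_stream <- function(stream, rotation, window_ms = 1000,
                         noise_stat = c("magnitude", "per_axis")) {
  noise_stat <- match.arg(noise_stat)
  calibrated <- apply_calibration(rotation, stream)
  cleaned <- remove_noise(calibrated, window_ms = window_ms, stat = noise_stat)
  if (nrow(cleaned) == 0) abort("No records remain after noise removal.")
  feats <- window_means(cleaned, window_ms = window_ms)
  tibble(window_index = feats$window_index, posture = label_posture(feats))
}

#' Write per-window posture labels to CSV
#'
#' @param labels Tibble with `window_index, posture`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(
    tibble(window_index = labels$window_index,
           posture = as.character(labels$posture)),
    path
  )
  invisible(path)
}

#' Read per-window posture labels from CSV
#'
#' @param path Path to a CSV with header `window_index,posture`.
#' @return Tibble with `window_index, posture` (posture factor).
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    window_index = readr::col_integer(), posture = readr::col_character()
  ))
  tibble(window_index = df$window_index, posture = as_posture(df$posture))
}
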