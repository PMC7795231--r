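# Synthetic paired chest/wrist sessions with known posture ground truth.
# Chest samples are the posture's canonical gravity direction, rotated in
# the X-Y plane by an (uncalibrated) mount angle, plus Gaussian noise.
# Wrist samples follow a posture-conditioned orientation that is redrawn
# every second (the wrist is not rigidly coupled to the trunk), plus noise.

#' Canonical chest gravity direction of a posture
#'
#' In the calibrated frame gravity loads: X for standing, +/-Y' for
#' left/right lateral, +/-Z for supine/prone.
#'
#' @param posture Posture name(s).
#' @return Matrix with one unit row `(x, y, z)` per posture.
#' @export
#' @examples
#' canonical_chest_gravity("Supine")
canonical_chest_gravity <- function(posture) {
  lut <- rbind(
    Stand        = c(1, 0, 0),
    Supine       = c(0, 0, 1),
    RightLateral = c(0, -1, 0),
    LeftLateral  = c(0, 1, 0),
    Prone        = c(0, 0, -1)
  )
  colnames(lut) <- c("x", "y", "z")
  p <- as.character(as_posture(posture))
  lut[p, , drop = FALSE]
}

# Default wrist orientation means: one unit vector per posture, pairwise at
# least 90 degrees apart.
default_wrist_means <- function() {
  canonical_chest_gravity(.posture_levels)
}

#' Describe a synthetic two-sensor sleep session
#'
#' @param posture_sequence Tibble/data frame with columns `posture` and
#'   `dwell_s` (> 0): the bout schedule.
#' @param sample_rate_hz Sampling rate (default 60).
#' @param noise_sd_g Per-axis Gaussian sensor noise sd in G (default 0.05).
#' @param chest_mount_angle_rad Planar rotation of the chest sensor as worn;
#'   `NULL` (default) draws it uniformly in (-pi, pi] at simulation time.
#' @param wrist_orientation_means 5 x 3 matrix of per-posture unit wrist
#'   orientations (rows named by posture).
#' @param wrist_orientation_sd Per-posture angular dispersion of the wrist
#'   orientation, redrawn each second; scalar or named vector (default 0.1).
#' @param overlap In `[0, 1)`: mixes Prone's wrist mean toward
#'   RightLateral's, emulating the overlapping right-wrist position that
#'   makes prone the most confusable posture (default 0).
#' @param glitch_rate Per-sample probability of a spurious record with
#'   magnitude below 0.01 G (default 0).
#' @param seed Integer seed (default 1).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(posture_sequence,
                              sample_rate_hz = 60,
                              noise_sd_g = 0.05,
                              chest_mount_angle_rad = NULL,
                              wrist_orientation_means = default_wrist_means(),
                              wrist_orientation_sd = 0.1,
                              overlap = 0,
                              glitch_rate = 0,
                              seed = 1L) {
  ps <- as_tibble(posture_sequence)
  stopifnot(all(c("posture", "dwell_s") %in% names(ps)))
  ps$posture <- as_posture(ps$posture)
  if (any(ps$dwell_s <= 0)) abort("All dwell_s must be positive.")
  stopifnot(
    sample_rate_hz > 0, noise_sd_g >= 0,
    overlap >= 0, overlap < 1,
    glitch_rate >= 0, glitch_rate <= 1
  )
  wm <- as.matrix(wrist_orientation_means)
  if (is.null(rownames(wm)) || !all(.posture_levels %in% rownames(wm))) {
    abort("wrist_orientation_means must have one named row per posture.")
  }
  norms <- sqrt(rowSums(wm^2))
  if (any(abs(norms - 1) > 1e-8)) abort("wrist_orientation_means rows must be unit vectors.")
  if (length(wrist_orientation_sd) == 1 && is.null(names(wrist_orientation_sd))) {
    wrist_orientation_sd <- setNames(
      rep(wrist_orientation_sd, length(.posture_levels)), .posture_levels
    )
  }
  if (!all(.posture_levels %in% names(wrist_orientation_sd))) {
    abort("wrist_orientation_sd must cover every posture.")
  }
  if (!is.null(chest_mount_angle_rad)) {
    stopifnot(chest_mount_angle_rad > -pi, chest_mount_angle_rad <= pi)
  }
  structure(
    list(
      posture_sequence = ps,
      sample_rate_hz = sample_rate_hz,
      noise_sd_g = noise_sd_g,
      chest_mount_angle_rad = chest_mount_angle_rad,
      wrist_orientation_means = wm[.posture_levels, , drop = FALSE],
      wrist_orientation_sd = wrist_orientation_sd[.posture_levels],
      overlap = overlap,
      glitch_rate = glitch_rate,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Ready-made simulation profiles
#'
#' `separable`: per-posture wrist orientations pairwise at least 90 degrees
#' apart, no overlap — the pipeline should learn this comfortably.
#' `confusable`: Prone's wrist mean mixed 0.6 toward RightLateral's and a
#' larger Prone orientation dispersion, reproducing the prone-confusion
#' phenomenon (the right wrist can sit almost identically in both postures).
#'
#' @param profile `"separable"` or `"confusable"`.
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
default_config <- function(profile = c("separable", "confusable"), seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "separable") {
    simulation_config(
      posture_sequence = tibble(
        posture = c("Stand", "Supine", "RightLateral", "LeftLateral", "Prone",
                    "Supine", "LeftLateral", "RightLateral", "Prone"),
        dwell_s = c(30, 60, 60, 60, 60, 60, 60, 60, 60)
      ),
      wrist_orientation_sd = 0.1,
      overlap = 0,
      glitch_rate = 0.002,
      seed = seed
    )
  } else {
    sds <- setNames(rep(0.15, 5), .posture_levels)
    sds["Prone"] <- 0.35
    # prone gets half the dwell of the other lying postures: in the
    # overlapped wrist region the majority class (right lateral) wins,
    # which is what tilts the confusion against prone
    simulation_config(
      posture_sequence = tibble(
        posture = c("Stand", "Supine", "RightLateral", "LeftLateral", "Prone",
                    "Supine", "LeftLateral", "RightLateral", "Prone"),
        dwell_s = c(30, 60, 60, 60, 30, 60, 60, 60, 30)
      ),
      wrist_orientation_sd = sds,
      overlap = 0.6,
      glitch_rate = 0.002,
      seed = seed
    )
  }
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Simulate a paired chest/wrist session
#'
#' Generates both sensor streams sample by sample from the bout schedule,
#' plus the per-window ground-truth labels (majority posture by sample
#' count; ties toward the earlier posture). Fully reproducible from the
#' config's seed. Output accelerations are clipped to the sensor range
#' [-2, 2] G (clips are reported).
#'
#' @param config A [simulation_config()].
#' @param windowsize_ms Window length used for the ground truth (default
#'   1000).
#' @return A `simulated_session`: list with `chest` and `wrist`
#'   [sensor_stream()]s, `truth` (tibble `window_index, posture`), the
#'   realised `mount_angle_rad`, and the `config`.
#' @export
simulate_session <- function(config, windowsize_ms = 1000) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    rate <- config$sample_rate_hz
    total_ms <- sum(config$posture_sequence$dwell_s) * 1000
    n <- floor(total_ms * rate / 1000)
    ts <- as.integer(floor((seq_len(n) - 1) * 1000 / rate))
    bout_end <- cumsum(config$posture_sequence$dwell_s) * 1000
    bout_of <- findInterval(ts, c(0, head(bout_end, -1)))
    posture <- config$posture_sequence$posture[bout_of]

    mount <- config$chest_mount_angle_rad
    if (is.null(mount)) mount <- runif(1, -pi, pi)

    # chest: rotate canonical gravity by the mount angle in the X-Y plane
    g <- canonical_chest_gravity(posture)
    cm <- cos(mount); sm <- sin(mount)
    chest <- cbind(
      g[, 1] * cm - g[, 2] * sm,
      g[, 1] * sm + g[, 2] * cm,
      g[, 3]
    ) + matrix(rnorm(3 * n, sd = config$noise_sd_g), ncol = 3)

    # wrist: posture-conditioned orientation redrawn once per second
    means <- config$wrist_orientation_means
    if (config$overlap > 0) {
      means["Prone", ] <- .unit(
        (1 - config$overlap) * means["Prone", ] +
          config$overlap * means["RightLateral", ]
      )
    }
    sec <- ts %/% 1000L
    wrist_mu <- matrix(0, nrow = n, ncol = 3)
    for (s in unique(sec)) {
      ii <- which(sec == s)
      p <- as.character(posture[ii[1]]) # orientation follows the bout at window start
      orient <- .unit(
        means[p, ] + rnorm(3, sd = config$wrist_orientation_sd[[p]])
      )
      wrist_mu[ii, ] <- matrix(orient, nrow = length(ii), ncol = 3, byrow = TRUE)
    }
    wrist <- wrist_mu + matrix(rnorm(3 * n, sd = config$noise_sd_g), ncol = 3)

    # glitch artifacts: spurious near-zero-magnitude records
    inject_glitches <- function(m) {
      hit <- which(runif(n) < config$glitch_rate)
      for (i in hit) {
        d <- .unit(rnorm(3))
        m[i, ] <- d * runif(1, 0, 0.01)
      }
      m
    }
    if (config$glitch_rate > 0) {
      chest <- inject_glitches(chest)
      wrist <- inject_glitches(wrist)
    }

    clips <- sum(chest < -2 | chest > 2) + sum(wrist < -2 | wrist > 2)
    if (clips > 0) {
      inform(sprintf("simulate_session: clipped %d sample value(s) to [-2, 2] G.", clips))
      chest[chest > 2] <- 2; chest[chest < -2] <- -2
      wrist[wrist > 2] <- 2; wrist[wrist < -2] <- -2
    }

    # ground truth: majority posture per complete window (ties -> earlier bout)
    win <- ts %/% as.integer(windowsize_ms) + 1L
    complete <- as.integer(seq_len(total_ms %/% windowsize_ms))
    truth <- tibble(window_index = win, posture = posture) |>
      filter(.data$window_index %in% complete) |>
      group_by(.data$window_index) |>
      summarise(posture = {
        tab <- table(.data$posture)[as.character(unique(.data$posture))]
        names(tab)[which.max(tab)]
      }, .groups = "drop") |>
      mutate(posture = as_posture(.data$posture))

    structure(
      list(
        chest = sensor_stream(
          tibble(timestamp_ms = ts, ax = chest[, 1], ay = chest[, 2], az = chest[, 3]),
          site = "chest", nominal_rate_hz = rate
        ),
        wrist = sensor_stream(
          tibble(timestamp_ms = ts, ax = wrist[, 1], ay = wrist[, 2], az = wrist[, 3]),
          site = "wrist", nominal_rate_hz = rate
        ),
        truth = truth,
        mount_angle_rad = mount,
        config = config
      ),
      class = "simulated_session"
    )
  })
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf(
    "Simulated session: %d chest / %d wrist records, %d truth windows, mount angle %.3f rad\n",
    nrow(x$chest), nrow(x$wrist), nrow(x$truth), x$mount_angle_rad
  ))
  invisible(x)
}
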