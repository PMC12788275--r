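# Per-participant raw-stream simulators. Each is deterministic given
# (truth row, config): it derives a private RNG stream from the cohort seed,
# the participant index and a stream tag, and restores the caller's RNG.

STREAM_GPS <- 1L
STREAM_STEPS <- 2L
STREAM_ACCEL <- 3L
STREAM_REPORTS <- 4L
STREAM_DEFICITS <- 5L

EARTH_RADIUS_M <- 6371000

# First-order Gauss-Markov positional error (metres), stationary sd `sd`,
# correlation time `tau` seconds. tau = 0 degenerates to white noise.
fogm_noise <- function(n, sd, tau, dt) {
  if (n == 0L || sd == 0) return(numeric(n))
  if (tau <= 0) return(rnorm(n, 0, sd))
  phi <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n - 1L, 0, sd * sqrt(1 - phi^2))
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + innov[i]
  x
}

# Local east/north displacement (metres) applied to WGS84 coordinates.
offset_lonlat <- function(lon, lat, east, north) {
  lat2 <- lat + north / EARTH_RADIUS_M * 180 / pi
  lon2 <- lon + east / (EARTH_RADIUS_M * cos(lat * pi / 180)) * 180 / pi
  cbind(lon = lon2, lat = lat2)
}

# Piecewise-straight track at constant speed: a new bearing every
# `turn_interval` seconds, coordinates stepped along great circles so that
# consecutive haversine distances are exactly speed * dt.
walking_track <- function(start_lonlat, n_points, speed, dt, turn_interval,
                          heading_sd) {
  bearing <- runif(1, 0, 360)
  pts <- matrix(NA_real_, n_points, 2)
  pos <- start_lonlat
  done <- 0L
  seg_len <- max(1L, round(turn_interval / dt))
  while (done < n_points) {
    k <- min(seg_len, n_points - done)
    seg <- geosphere::destPoint(pos, bearing, speed * dt * seq_len(k),
                                r = EARTH_RADIUS_M)
    pts[done + seq_len(k), ] <- seg
    pos <- seg[k, ]
    done <- done + k
    bearing <- (bearing + rnorm(1, 0, heading_sd)) %% 360
  }
  pts
}

# Non-overlapping daily event schedule: each event occupies its own clock
# hour (08:00-20:00 local), guaranteeing inter-event gaps > 300 s.
schedule_events <- function(n_events, day_start_local, max_duration) {
  hours <- sample(8:20, min(n_events, 13L))
  starts <- day_start_local + hours * 3600 +
    floor(runif(length(hours), 0, max(1, 3600 - max_duration - 400)))
  sort(starts)
}

#' Simulate a labeled GPS log for one participant
#'
#' Emits a two-week style log of (timestamp, latitude, longitude, activity)
#' samples: walking bouts at the participant's true gait speed along
#' piecewise-straight tracks, in-vehicle segments faster than 2 m/s, and
#' stationary segments, all corrupted by temporally correlated GPS positional
#' noise and by activity-label errors at `config$mislabel_rate` (walking
#' points lose the Walking label; vehicle and still points occasionally gain
#' it). Timestamps are strictly increasing. Participants whose gait stream is
#' flagged unavailable yield an empty log.
#'
#' @param truth One row of a [generate_cohort()] data.frame.
#' @param config The [cohort_config()] used to generate the cohort.
#' @return data.frame with columns `t` (UTC epoch seconds), `lat`, `lon`,
#'   `activity` (one of WALKING, ON_FOOT, IN_VEHICLE, STILL, OTHER).
#' @export
simulate_gps_log <- function(truth, config) {
  if (config$sampling_interval <= 0)
    fl_config_error("sampling_interval must be > 0")
  empty <- data.frame(t = numeric(0), lat = numeric(0), lon = numeric(0),
                      activity = character(0), stringsAsFactors = FALSE)
  if (!isTRUE(truth$gait_available) || config$days == 0L) return(empty)

  with_stream_seed(stream_seed(config$seed, truth$idx, STREAM_GPS), {
    dt <- config$sampling_interval
    home <- geosphere::destPoint(c(config$base_lon, config$base_lat),
                                 runif(1, 0, 360), runif(1, 0, 2000),
                                 r = EARTH_RADIUS_M)
    logs <- list()
    for (d in seq_len(config$days)) {
      day_local <- config$start_epoch + config$tz_offset + (d - 1L) * 86400
      n_bouts <- rpois(1, config$bouts_per_day)
      n_veh <- rpois(1, config$vehicle_per_day)
      n_still <- rpois(1, config$still_per_day)
      kinds <- c(rep("walk", n_bouts), rep("vehicle", n_veh),
                 rep("still", n_still))
      if (!length(kinds)) next
      kinds <- sample(kinds)
      starts <- schedule_events(length(kinds), day_local,
                                max(config$bout_duration_s,
                                    config$vehicle_duration_s,
                                    config$still_duration_s))
      kinds <- kinds[seq_along(starts)]
      for (e in seq_along(starts)) {
        dur <- switch(kinds[e], walk = config$bout_duration_s,
                      vehicle = config$vehicle_duration_s,
                      still = config$still_duration_s)
        n_pts <- max(2L, floor(dur / dt))
        start_pos <- geosphere::destPoint(home, runif(1, 0, 360),
                                          runif(1, 0, 1500),
                                          r = EARTH_RADIUS_M)
        pts <- switch(kinds[e],
          walk = walking_track(start_pos, n_pts, truth$true_gait_speed, dt,
                               config$turn_interval_s,
                               config$heading_change_sd),
          vehicle = walking_track(start_pos, n_pts, config$vehicle_speed, dt,
                                  config$turn_interval_s, 5),
          still = matrix(rep(start_pos, each = n_pts), n_pts, 2))
        label <- switch(kinds[e], walk = "WALKING", vehicle = "IN_VEHICLE",
                        still = "STILL")
        labels <- rep(label, n_pts)
        flip <- runif(n_pts) < config$mislabel_rate
        if (label == "WALKING") {
          labels[flip] <- sample(c("ON_FOOT", "STILL", "OTHER"), sum(flip),
                                 replace = TRUE)
        } else {
          labels[flip] <- "WALKING"
        }
        east <- fogm_noise(n_pts, config$gps_noise_sd,
                           config$gps_noise_corr_time, dt)
        north <- fogm_noise(n_pts, config$gps_noise_sd,
                            config$gps_noise_corr_time, dt)
        noisy <- offset_lonlat(pts[, 1], pts[, 2], east, north)
        logs[[length(logs) + 1L]] <- data.frame(
          t = (starts[e] - config$tz_offset) + (seq_len(n_pts) - 1L) * dt,
          lat = noisy[, "lat"], lon = noisy[, "lon"], activity = labels,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(logs)) return(empty)
    out <- do.call(rbind, logs)
    out[order(out$t), , drop = FALSE]
  })
}

#' Simulate timestamped pedometer records for one participant
#'
#' Hourly step counts follow a bursty diurnal process: each day has a
#' lognormal day-level multiplier, a small number of active hours (mean
#' `config$active_hours_mean`) drawn from a daytime profile, and the day
#' total (mean `true_daily_steps`) is split across them with overdispersion.
#' Days whose total is zero still emit a single zero-step record so that
#' worn-but-inactive days enter the daily mean as zeros.
#'
#' @inheritParams simulate_gps_log
#' @return data.frame with columns `t` (UTC epoch seconds, local hour starts)
#'   and `steps` (nonnegative integers).
#' @export
simulate_pedometer <- function(truth, config) {
  if (config$days < 0) fl_config_error("days must be >= 0")
  empty <- data.frame(t = numeric(0), steps = integer(0))
  if (!isTRUE(truth$steps_available) || config$days == 0L) return(empty)

  with_stream_seed(stream_seed(config$seed, truth$idx, STREAM_STEPS), {
    hours <- 6:21
    profile <- dnorm(hours, 10, 2.2) + dnorm(hours, 16.5, 2.6)
    profile <- profile / sum(profile)
    recs <- list()
    for (d in seq_len(config$days)) {
      day_local <- config$start_epoch + config$tz_offset + (d - 1L) * 86400
      mult <- rlnorm(1, -config$day_effect_sd^2 / 2, config$day_effect_sd)
      total <- rpois(1, truth$true_daily_steps * mult)
      if (total == 0) {
        recs[[length(recs) + 1L]] <- data.frame(
          t = day_local + 12 * 3600 - config$tz_offset, steps = 0L)
        next
      }
      n_act <- min(length(hours), 1L + rpois(1, config$active_hours_mean - 1))
      act <- sample(hours, n_act, prob = profile)
      wts <- rgamma(n_act, shape = 1.2)
      alloc <- as.vector(rmultinom(1, total, wts / sum(wts)))
      keep <- alloc > 0
      if (!any(keep)) next
      recs[[length(recs) + 1L]] <- data.frame(
        t = day_local + sort(act[keep]) * 3600 - config$tz_offset,
        steps = as.integer(alloc[keep][order(act[keep])]))
    }
    if (!length(recs)) return(empty)
    do.call(rbind, recs)
  })
}

#' Simulate a 30-second chair-stand accelerometer trace
#'
#' Vertical acceleration over a 30 s instructed sit-to-stand task containing
#' exactly `true_sts_reps` oscillation cycles of amplitude
#' `config$accel_amplitude` plus Gaussian noise, sampled at
#' `config$accel_rate` Hz. Returns `NULL` when the chair-stand stream is
#' flagged unavailable.
#'
#' @inheritParams simulate_gps_log
#' @return List of class `fl_accel_trace` with `t` (seconds), `az` (m/s^2)
#'   and `rate` (Hz), or `NULL`.
#' @export
simulate_sts_accel <- function(truth, config) {
  if (truth$true_sts_reps < 0) fl_config_error("true_sts_reps must be >= 0")
  if (!isTRUE(truth$sts_available)) return(NULL)
  with_stream_seed(stream_seed(config$seed, truth$idx, STREAM_ACCEL), {
    n <- 30L * config$accel_rate
    t <- (seq_len(n) - 1L) / config$accel_rate
    signal <- if (truth$true_sts_reps > 0)
      config$accel_amplitude * sin(2 * pi * truth$true_sts_reps * t / 30)
    else rep(0, n)
    structure(list(t = t, az = signal + rnorm(n, 0, config$accel_noise_sd),
                   rate = config$accel_rate),
              class = "fl_accel_trace")
  })
}

#' Simulate daily self-reports for one participant
#'
#' Daily RPE (1-15) and subjective health (1-4, higher = worse) integers
#' drawn from rounded ordinal models centered on the participant's true
#' levels, with per-day response probability `config$report_prob` and
#' per-feature availability flags. With zero noise every report equals the
#' rounded true level.
#'
#' @inheritParams simulate_gps_log
#' @return data.frame with columns `day`, `date` (local ISO date), `rpe`,
#'   `health`; unanswered or unavailable entries are NA.
#' @export
simulate_self_reports <- function(truth, config) {
  if (config$days < 0) fl_config_error("days must be >= 0")
  with_stream_seed(stream_seed(config$seed, truth$idx, STREAM_REPORTS), {
    d <- seq_len(config$days)
    draw <- function(level, noise_sd, lo, hi, available) {
      if (!isTRUE(available)) return(rep(NA_integer_, length(d)))
      v <- as.integer(pmin(pmax(round(level + rnorm(length(d), 0, noise_sd)),
                                lo), hi))
      v[runif(length(d)) >= config$report_prob] <- NA_integer_
      v
    }
    data.frame(
      day = d,
      date = format(as.Date("1970-01-01") +
                      floor((config$start_epoch + config$tz_offset) / 86400) +
                      (d - 1L)),
      rpe = draw(truth$true_rpe_level, config$rpe_noise_sd, 1L, 15L,
                 truth$rpe_available),
      health = draw(truth$true_health_level, config$health_noise_sd, 1L, 4L,
                    truth$health_available),
      stringsAsFactors = FALSE)
  })
}

# Deficit values for every participant at once (rows = participants).
simulate_deficit_matrix <- function(truths, config) {
  calib <- attr(truths, "calibration")
  if (is.null(calib)) calib <- get_fi_calib(config)
  reg <- config$registry
  n <- nrow(truths)
  n_item <- nrow(reg)
  vals <- matrix(NA_real_, n, n_item, dimnames = list(truths$id, reg$name))
  if (n == 0L) return(vals)
  # item-level thresholds on the u = z + s*eps scale (participant-invariant)
  thr <- lapply(seq_len(n_item), function(i) {
    cut <- qnorm(pmin(cumsum(reg$prev[[i]]), 1)) * sqrt(1 + calib$s^2)
    cut[-length(cut)]
  })
  lev <- reg$levels
  for (p in seq_len(n)) {
    u <- with_stream_seed(
      stream_seed(config$seed, truths$idx[p], STREAM_DEFICITS),
      truths$latent_frailty[p] + calib$s * rnorm(n_item))
    for (i in seq_len(n_item))
      vals[p, i] <- lev[[i]][findInterval(u[i], thr[[i]],
                                          left.open = TRUE) + 1L]
  }
  vals
}

#' Simulate a deficit profile for one participant
#'
#' Draws the 50 registry items from a probit item model on the latent
#' frailty factor: item `i` takes the deficit level whose threshold band
#' contains `latent_frailty + s * noise`, where the item-noise scale `s` is
#' calibrated so the implied FI standard deviation matches `config$fi_sd`
#' (see [fi_planted_moments()]). Binary items are therefore Bernoulli with a
#' propensity nondecreasing in latent frailty; graded items land on their
#' admissible level sets.
#'
#' @inheritParams simulate_gps_log
#' @return Named numeric vector of deficit values (length = registry size).
#' @export
simulate_deficits <- function(truth, config) {
  simulate_deficit_matrix(truth, config)[1, ]
}
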