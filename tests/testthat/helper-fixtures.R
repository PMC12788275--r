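# Fixture builders shared across test files. Everything is generated in code.

# GPS log data.frame from parallel vectors.
gps_df <- function(t, lat, lon, activity = "WALKING") {
  data.frame(t = t, lat = lat, lon = lon,
             activity = rep_len(activity, length(t)),
             stringsAsFactors = FALSE)
}

# n points along a meridian at constant speed (m/s), 1 s apart: the
# northward displacement per second is exactly speed / R radians.
meridian_track <- function(n, speed = 1.2, lat0 = 37.5, lon0 = 127,
                           t0 = 0, dt = 1) {
  dlat_deg <- speed * dt / 6371000 * 180 / pi
  gps_df(t = t0 + (seq_len(n) - 1) * dt,
         lat = lat0 + (seq_len(n) - 1) * dlat_deg,
         lon = rep(lon0, n))
}

# Full-availability small-cohort config for fast end-to-end tests.
fast_config <- function(n = 20, seed = 1, days = 3, ...) {
  cohort_config(
    n_participants = n, seed = seed, days = days,
    missingness_map = c(gait_speed = 1, sts_counts = 1, daily_steps = 1,
                        rpe = 1, subjective_health = 1),
    ...)
}

# A clean chair-stand trace with `reps` cycles at the given noise sd.
sts_trace <- function(reps, noise_sd = 0, rate = 50, amplitude = 2,
                      seed = 1) {
  n <- 30L * rate
  t <- (seq_len(n) - 1L) / rate
  az <- if (reps > 0) amplitude * sin(2 * pi * reps * t / 30) else rep(0, n)
  if (noise_sd > 0) {
    set.seed(seed)
    az <- az + rnorm(n, 0, noise_sd)
  }
  structure(list(t = t, az = az, rate = rate), class = "fl_accel_trace")
}

# Seeded regression fixture: y = X b + noise.
reg_fixture <- function(n = 30, k = 3, seed = 1, sigma = 1,
                        beta = seq_len(k)) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * k), n, k,
                            dimnames = list(NULL, paste0("x", seq_len(k)))))
  y <- as.matrix(X) %*% beta + rnorm(n, 0, sigma)
  list(y = as.vector(y), X = X, beta = beta)
}
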