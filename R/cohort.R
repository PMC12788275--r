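# Synthetic cohort: a latent frailty factor drives deficit items, lifelog
# behaviour and clinical covariates with configurable planted effect sizes.
#
# Effect sizes are specified on the observable scale -- the Pearson
# correlation between the Frailty Index and each feature -- because those are
# the quantities a cohort of this design exhibits and reports. Internally each
# feature is linked to the latent factor through a Gaussian copula whose
# loading is calibrated by quadrature so that the planted FI-feature
# correlation is attained in the large-sample limit.

#' Configuration for the synthetic lifelog cohort
#'
#' Bundles every knob of the generator with validated defaults that emulate a
#' two-week smartphone lifelogging study of ~300 community-dwelling older
#' adults: planted FI-feature correlations default to the observed magnitudes
#' (gait speed -0.370, chair-stand counts -0.224, daily steps -0.119, RPE
#' 0.135, subjective health 0.232), and per-feature availability defaults to
#' the observed counts out of 300 (94, 253, 290, 248, 255).
#'
#' @param n_participants Number of participants (>= 0).
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   cohorts.
#' @param days Days of lifelog collection.
#' @param effect_map Named vector of planted FI-feature correlations in
#'   (-1, 1) for `gait_speed`, `sts_counts`, `daily_steps`, `rpe`,
#'   `subjective_health`. Hourly steps are not independently planted; their
#'   association emerges from daily steps and the active-hour process.
#' @param missingness_map Named vector of per-feature availability
#'   probabilities in \[0, 1\] (same names as `effect_map`; `daily_steps`
#'   governs the whole pedometer stream, so hourly steps share it).
#' @param covariate_effect_map Planted FI-covariate correlations for `age`,
#'   `sex`, `height`, `weight`, `smm`, `fat_pct`, `sppb`.
#' @param gps_noise_sd Stationary GPS positional error, metres (per axis).
#' @param gps_noise_corr_time Correlation time of the first-order
#'   Gauss-Markov GPS error process, seconds. `0` gives white noise.
#' @param sampling_interval GPS sampling interval, seconds.
#' @param bouts_per_day Poisson mean of walking bouts per day.
#' @param bout_duration_s Walking bout length, seconds.
#' @param turn_interval_s,heading_change_sd Walking tracks are
#'   piecewise-straight; a new bearing is drawn every `turn_interval_s`
#'   seconds with sd `heading_change_sd` degrees.
#' @param mislabel_rate Probability that an activity label is corrupted
#'   (walking points lose the label; vehicle/still points may gain it).
#' @param vehicle_per_day,vehicle_speed,vehicle_duration_s Interleaved
#'   in-vehicle segments (count per day, m/s, seconds).
#' @param still_per_day,still_duration_s Interleaved stationary segments.
#' @param base_lat,base_lon Home base, WGS84 degrees.
#' @param accel_rate,accel_amplitude,accel_noise_sd Chair-stand trace:
#'   sampling rate (Hz), oscillation amplitude and noise sd (m/s^2).
#' @param rpe_noise_sd,health_noise_sd Daily self-report noise on the latent
#'   ordinal scales.
#' @param report_prob Daily probability that a self-report is filled in.
#' @param day_effect_sd Lognormal sd of the day-level step multiplier.
#' @param active_hours_mean Mean number of step-active hours per day.
#' @param fi_sd Target population sd of the Frailty Index; the deficit-item
#'   noise scale is calibrated to it.
#' @param fi_item_noise Optional fixed deficit-item noise scale; when given,
#'   no calibration to `fi_sd` is performed (useful for degenerate
#'   registries).
#' @param registry Deficit item registry, see [fi_registry()].
#' @param tz_offset Local-time offset from UTC in seconds (default +09:00).
#' @param start_epoch UTC epoch seconds of local midnight on study day 1.
#' @return A validated list of class `fl_cohort_config`.
#' @export
cohort_config <- function(
    n_participants = 300,
    seed = 1,
    days = 14,
    effect_map = c(gait_speed = -0.370, sts_counts = -0.224,
                   daily_steps = -0.119, rpe = 0.135,
                   subjective_health = 0.232),
    missingness_map = c(gait_speed = 94 / 300, sts_counts = 253 / 300,
                        daily_steps = 290 / 300, rpe = 248 / 300,
                        subjective_health = 255 / 300),
    covariate_effect_map = c(age = 0.10, sex = 0.05, height = -0.05,
                             weight = 0.05, smm = -0.10, fat_pct = 0.10,
                             sppb = -0.22),
    gps_noise_sd = 5,
    gps_noise_corr_time = 300,
    sampling_interval = 1,
    bouts_per_day = 2,
    bout_duration_s = 900,
    turn_interval_s = 60,
    heading_change_sd = 25,
    mislabel_rate = 0.02,
    vehicle_per_day = 1,
    vehicle_speed = 12,
    vehicle_duration_s = 600,
    still_per_day = 2,
    still_duration_s = 120,
    base_lat = 37.55,
    base_lon = 126.97,
    accel_rate = 50,
    accel_amplitude = 2,
    accel_noise_sd = 0.2,
    rpe_noise_sd = 1.5,
    health_noise_sd = 0.45,
    report_prob = 0.9,
    day_effect_sd = 0.35,
    active_hours_mean = 4.4,
    fi_sd = 0.069,
    fi_item_noise = NULL,
    registry = fi_registry(),
    tz_offset = 9 * 3600,
    start_epoch = 1696086000) {

  cfg <- as.list(environment())
  if (!is_count(n_participants)) fl_config_error("n_participants must be a
    nonnegative integer count")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    fl_config_error("seed must be a single integer")
  if (!is_count(days)) fl_config_error("days must be a nonnegative count")
  if (sampling_interval <= 0) fl_config_error("sampling_interval must be > 0")
  probs <- c(missingness_map, mislabel_rate, report_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    fl_config_error("all probabilities must lie in [0, 1]")
  cors <- c(effect_map, covariate_effect_map)
  if (any(!is.finite(cors)) || any(abs(cors) >= 1))
    fl_config_error("all planted correlations must lie in (-1, 1)")
  need <- c("gait_speed", "sts_counts", "daily_steps", "rpe",
            "subjective_health")
  if (!all(need %in% names(effect_map)) ||
      !all(need %in% names(missingness_map)))
    fl_config_error(paste("effect_map and missingness_map must name:",
                          paste(need, collapse = ", ")))
  if (fi_sd <= 0) fl_config_error("fi_sd must be positive")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "fl_cohort_config"
  cfg
}

# ---- calibration machinery -------------------------------------------------

# Quadrature grid over the latent standard-normal factor.
latent_grid <- function(n = 601, lim = 7) {
  z <- seq(-lim, lim, length.out = n)
  w <- dnorm(z)
  list(z = z, w = w / sum(w))
}

# Per-item conditional moments of the deficit value given latent z, under the
# probit item model: item level determined by u = z + s * eps crossing
# thresholds placed to reproduce the item's marginal level prevalences.
item_conditional_moments <- function(levels, prev, s, z) {
  cum <- cumsum(prev)
  thr <- qnorm(pmin(cum, 1)) * sqrt(1 + s^2)   # on the u scale
  k <- length(levels)
  upper <- outer(z, thr[-k], function(zz, tt) pnorm((tt - zz) / s))
  p <- cbind(upper, 1) - cbind(0, upper)       # n_z x k level probabilities
  list(m = as.vector(p %*% levels), m2 = as.vector(p %*% levels^2))
}

# Implied population moments of the FI for item-noise scale s.
fi_implied_moments <- function(registry, s, grid = latent_grid()) {
  z <- grid$z; w <- grid$w
  n_item <- nrow(registry)
  m_sum <- rep(0, length(z)); v_sum <- rep(0, length(z))
  for (i in seq_len(n_item)) {
    mom <- item_conditional_moments(registry$levels[[i]], registry$prev[[i]],
                                    s, z)
    m_sum <- m_sum + mom$m
    v_sum <- v_sum + (mom$m2 - mom$m^2)
  }
  m_z <- m_sum / n_item                       # E[FI | z]
  cond_var <- v_sum / n_item^2                # Var[FI | z], items independent
  mean_fi <- sum(m_z * w)
  var_fi <- sum((m_z - mean_fi)^2 * w) + sum(cond_var * w)
  cov_z <- sum(z * m_z * w)
  list(mean = mean_fi, sd = sqrt(var_fi),
       rho = if (var_fi > 0) cov_z / sqrt(var_fi) else 0,
       propensity = list(z = z, m = m_z))
}

# Calibration for a config: either solve the item-noise scale from the
# target FI sd, or honour an explicit fi_item_noise override.
get_fi_calib <- function(config) {
  if (!is.null(config$fi_item_noise)) {
    mom <- fi_implied_moments(config$registry, config$fi_item_noise)
    return(list(s = config$fi_item_noise, rho = mom$rho, mean = mom$mean,
                sd = mom$sd, propensity = mom$propensity))
  }
  fi_link_calibration(config$registry, config$fi_sd)
}

# Calibrate the item-noise scale so the implied FI sd matches the target.
fi_link_calibration <- function(registry, target_sd) {
  grid <- latent_grid()
  f <- function(s) fi_implied_moments(registry, s, grid)$sd - target_sd
  lo <- 0.05; hi <- 20
  if (f(lo) < 0 || f(hi) > 0)
    fl_config_error(sprintf(
      "target FI sd %.3f is outside the range attainable by the registry",
      target_sd))
  s <- uniroot(f, c(lo, hi), tol = 1e-6)$root
  mom <- fi_implied_moments(registry, s, grid)
  list(s = s, rho = mom$rho, mean = mom$mean, sd = mom$sd,
       propensity = mom$propensity)
}

# Predicted E[FI | latent z] under the calibrated link (the participant-level
# deficit propensity).
fi_propensity <- function(calib, z) {
  approx(calib$propensity$z, calib$propensity$m, xout = z, rule = 2)$y
}

# Orthonormal Hermite coefficients of f evaluated on a standard-normal grid:
# f(w) = sum_k coef_k h_k(w) with E[h_j(W) h_k(W)] = delta_jk.
hermite_coefs <- function(fvals, w, pw, K = 20) {
  h_prev <- rep(1, length(w))       # h_0
  h_cur <- w                        # h_1 (He_1 / sqrt(1!))
  coefs <- numeric(K)
  coefs[1] <- sum(fvals * h_cur * pw)
  for (k in 2:K) {
    # He_{k} = w He_{k-1} - (k-1) He_{k-2}; orthonormalized on the fly
    h_next <- (w * h_cur * sqrt(factorial(k - 1)) -
                 (k - 1) * h_prev * sqrt(factorial(k - 2))) /
      sqrt(factorial(k))
    coefs[k] <- sum(fvals * h_next * pw)
    h_prev <- h_cur
    h_cur <- h_next
  }
  coefs
}

# Calibrate the latent loading lambda of a feature with marginal quantile
# function `qfun` so that corr(FI, feature) equals `target`. Uses the Hermite
# expansion: with W = lambda Z + sqrt(1-lambda^2) eps and X = q(Phi(W)),
# Cov(X, FI) = sum_k a_k b_k lambda^k, where a_k are the Hermite
# coefficients of the marginal transform and b_k those of E[FI | Z].
copula_lambda <- function(qfun, target, calib, K = 20) {
  if (target == 0) return(0)
  w <- seq(-8, 8, length.out = 4001)
  pw <- dnorm(w); pw <- pw / sum(pw)
  x <- qfun(pnorm(w))
  mu <- sum(x * pw)
  sd_x <- sqrt(sum((x - mu)^2 * pw))
  a <- hermite_coefs(x, w, pw, K)
  z <- calib$propensity$z
  wz <- dnorm(z); wz <- wz / sum(wz)
  b <- hermite_coefs(calib$propensity$m, z, wz, K)
  cfun <- function(lam) sum(a * b * lam^seq_len(K)) / (sd_x * calib$sd)
  if (abs(cfun(sign(target) * 0.999)) < abs(target)) return(NA_real_)
  uniroot(function(l) cfun(l) - target, sort(c(0, sign(target) * 0.999)),
          tol = 1e-9)$root
}

# Marginal quantile functions of the lifelog features (population scale).
feature_marginals <- function() {
  lnorm_par <- function(mean, sd) {
    s2 <- log(1 + (sd / mean)^2)
    c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
  }
  lp <- lnorm_par(3343.93, 3049.45)
  list(
    gait_speed = function(u) qtruncnorm(u, 1.12, 0.13, 0.3, 2.0),
    sts_counts = function(u) qtruncnorm(u, 17.36, 5.12, 0, Inf),
    daily_steps = function(u) qlnorm(u, lp["mu"], lp["sigma"]),
    rpe = function(u) qtruncnorm(u, 5.88, 2.17, 1, 15),
    subjective_health = function(u) qtruncnorm(u, 2.05, 0.42, 1, 4)
  )
}

#' Model-implied moments of the synthetic Frailty Index
#'
#' Returns the generator's large-sample FI mean, sd and the correlation
#' between the latent frailty factor and the FI, computed by quadrature under
#' the calibrated item link. These are the planted values that sample
#' statistics of a generated cohort converge to.
#'
#' @param config A [cohort_config()].
#' @return List with `mean`, `sd`, `rho_latent_fi` and the calibrated item
#'   noise scale `item_noise`.
#' @export
fi_planted_moments <- function(config) {
  calib <- get_fi_calib(config)
  list(mean = calib$mean, sd = calib$sd, rho_latent_fi = calib$rho,
       item_noise = calib$s)
}

# ---- cohort generation -----------------------------------------------------

#' Generate a synthetic cohort of participant ground truths
#'
#' Draws `n_participants` latent frailty scores (standard normal) and, for
#' each participant, true behavioural parameters (usual gait speed, daily
#' steps, chair-stand repetitions, RPE and subjective-health levels), clinical
#' covariates, deficit propensity, and per-feature availability flags. The
#' planted FI-feature correlations of `config$effect_map` are attained in the
#' large-sample limit; correspondingly the latent-feature correlation is
#' `effect / rho_latent_fi` (see [fi_planted_moments()]).
#'
#' @param config A [cohort_config()].
#' @return data.frame of class `fl_cohort` with one row per participant and
#'   attributes `config` and `calibration`.
#' @export
#' @examples
#' truths <- generate_cohort(cohort_config(n_participants = 20, seed = 7))
#' head(truths[, c("id", "latent_frailty", "true_gait_speed")])
generate_cohort <- function(config) {
  if (!inherits(config, "fl_cohort_config"))
    fl_config_error("config must come from cohort_config()")
  n <- config$n_participants
  calib <- get_fi_calib(config)
  marg <- feature_marginals()

  with_stream_seed(config$seed, {
    z <- rnorm(n)

    draw_feature <- function(name, qfun, effect) {
      lam <- copula_lambda(qfun, effect, calib)
      if (!is.finite(lam) || abs(lam) >= 0.999)
        fl_config_error(sprintf(
          "planted correlation %.3f for %s is not attainable", effect, name))
      wl <- lam * z + sqrt(1 - lam^2) * rnorm(n)
      qfun(pnorm(wl))
    }

    em <- config$effect_map
    gait <- draw_feature("gait_speed", marg$gait_speed, em[["gait_speed"]])
    sts <- pmax(0, round(draw_feature("sts_counts", marg$sts_counts,
                                      em[["sts_counts"]])))
    steps <- draw_feature("daily_steps", marg$daily_steps,
                          em[["daily_steps"]])
    rpe <- draw_feature("rpe", marg$rpe, em[["rpe"]])
    health <- draw_feature("subjective_health", marg$subjective_health,
                           em[["subjective_health"]])

    cm <- config$covariate_effect_map
    lam_sex <- if (cm[["sex"]] == 0) 0 else cm[["sex"]] / calib$rho
    wsex <- lam_sex * z + sqrt(1 - lam_sex^2) * rnorm(n)
    female <- as.integer(wsex > qnorm(1 - 0.7933))

    cov_norm <- function(effect, mean_f, sd_f, mean_m, sd_m,
                         lo = -Inf, hi = Inf) {
      lam <- if (effect == 0) 0 else effect / calib$rho
      wl <- lam * z + sqrt(1 - lam^2) * rnorm(n)
      mu <- ifelse(female == 1, mean_f, mean_m)
      sdv <- ifelse(female == 1, sd_f, sd_m)
      pmin(pmax(mu + sdv * wl, lo), hi)
    }
    age <- cov_norm(cm[["age"]], 73.3, 5.37, 73.3, 5.37, 65, 95)
    height <- cov_norm(cm[["height"]], 154.8, 5.6, 164.5, 5.8)
    weight <- cov_norm(cm[["weight"]], 56.5, 8.8, 65.5, 10.5, 30, 120)
    smm <- cov_norm(cm[["smm"]], 19.8, 3.2, 27.5, 4.2, 8, 45)
    fat <- cov_norm(cm[["fat_pct"]], 33.5, 6.3, 23.6, 6.5, 5, 55)
    sppb <- round(cov_norm(cm[["sppb"]], 11.17, 1.52, 11.17, 1.52, 0, 12))

    mm <- config$missingness_map
    avail <- function(p) runif(n) < p

    out <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      idx = seq_len(n),
      latent_frailty = z,
      true_gait_speed = gait,
      true_daily_steps = steps,
      true_sts_reps = sts,
      true_rpe_level = rpe,
      true_health_level = health,
      deficit_propensity = fi_propensity(calib, z),
      age = age, sex = female, height = height, weight = weight,
      smm = smm, fat_pct = fat, sppb = sppb,
      gait_available = avail(mm[["gait_speed"]]),
      sts_available = avail(mm[["sts_counts"]]),
      steps_available = avail(mm[["daily_steps"]]),
      rpe_available = avail(mm[["rpe"]]),
      health_available = avail(mm[["subjective_health"]]),
      stringsAsFactors = FALSE
    )
    attr(out, "config") <- config
    attr(out, "calibration") <- calib
    class(out) <- c("fl_cohort", "data.frame")
    out
  })
}
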