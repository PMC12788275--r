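# Synthetic cohort generator: configuration contracts, determinism, planted
# effect sizes and the stream simulators.

test_that("configuration validation rejects malformed inputs", {
  expect_error(cohort_config(n_participants = -1), class = "frailtylog_config_error")
  expect_error(cohort_config(mislabel_rate = 1.5), class = "frailtylog_config_error")
  expect_error(cohort_config(effect_map = c(gait_speed = -1.2, sts_counts = 0,
                                            daily_steps = 0, rpe = 0,
                                            subjective_health = 0)),
               class = "frailtylog_config_error")
  expect_error(cohort_config(missingness_map = c(gait_speed = -0.1,
                                                 sts_counts = 1,
                                                 daily_steps = 1, rpe = 1,
                                                 subjective_health = 1)),
               class = "frailtylog_config_error")
  expect_error(cohort_config(sampling_interval = 0), class = "frailtylog_config_error")
})

test_that("empty cohort and determinism contracts hold", {
  expect_equal(nrow(generate_cohort(cohort_config(n_participants = 0))), 0L)

  cfg <- fast_config(n = 15, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(fast_config(n = 15, seed = 43))
  expect_false(identical(a$latent_frailty, c2$latent_frailty))

  # stream-level determinism: same (truth, config) -> identical raw streams
  expect_identical(simulate_gps_log(a[1, ], cfg), simulate_gps_log(b[1, ], cfg))
  expect_identical(simulate_pedometer(a[2, ], cfg),
                   simulate_pedometer(b[2, ], cfg))
  expect_identical(simulate_deficits(a[3, ], cfg),
                   simulate_deficits(b[3, ], cfg))
})

test_that("generator does not disturb the caller's RNG stream", {
  cfg <- fast_config(n = 5, seed = 9)
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(generate_cohort(cfg))
  invisible(simulate_gps_log(generate_cohort(cfg)[1, ], cfg))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("planted FI-feature correlations are recovered at n = 5000", {
  em <- c(gait_speed = -0.370, sts_counts = -0.224, daily_steps = -0.5,
          rpe = 0.135, subjective_health = 0.232)
  cfg <- cohort_config(n_participants = 5000, seed = 1, effect_map = em)
  truths <- generate_cohort(cfg)
  fi <- rowMeans(simulate_deficit_matrix(truths, cfg))

  expect_lt(abs(cor(fi, truths$true_daily_steps) - (-0.5)), 0.05)
  expect_lt(abs(cor(fi, truths$true_gait_speed) - (-0.370)), 0.05)
  expect_lt(abs(cor(fi, truths$true_health_level) - 0.232), 0.05)

  # FI moments match the quadrature-implied planted values
  mom <- fi_planted_moments(cfg)
  expect_lt(abs(mean(fi) - mom$mean), 0.01)
  expect_lt(abs(sd(fi) - mom$sd), 0.01)
  expect_lt(abs(cor(truths$latent_frailty, fi) - mom$rho_latent_fi), 0.05)

  # the latent factor correlates with each feature more strongly than the
  # FI does (the FI is a noisy readout of the latent factor)
  expect_lt(cor(truths$latent_frailty, truths$true_daily_steps), -0.5)
})

test_that("per-feature availability matches the missingness map", {
  cfg <- cohort_config(n_participants = 2000, seed = 7)
  truths <- generate_cohort(cfg)
  expected <- cfg$missingness_map
  observed <- c(gait_speed = mean(truths$gait_available),
                sts_counts = mean(truths$sts_available),
                daily_steps = mean(truths$steps_available),
                rpe = mean(truths$rpe_available),
                subjective_health = mean(truths$health_available))
  # three binomial sds at n = 2000
  tol <- 3 * sqrt(expected * (1 - expected) / 2000)
  expect_true(all(abs(observed - expected[names(observed)]) < tol))
})

test_that("deficit propensity is nondecreasing in latent frailty", {
  cfg <- fast_config(n = 200, seed = 3)
  truths <- generate_cohort(cfg)
  ord <- order(truths$latent_frailty)
  expect_true(all(diff(truths$deficit_propensity[ord]) >= -1e-12))
  expect_true(all(truths$true_gait_speed >= 0.3 &
                    truths$true_gait_speed <= 2.0))
})

test_that("GPS simulator honours bout structure, labels and noise settings", {
  cfg <- fast_config(n = 2, seed = 11, days = 2, gps_noise_sd = 0,
                     mislabel_rate = 0)
  truths <- generate_cohort(cfg)

  # no bouts -> no Walking-labeled points (label corruption off)
  cfg0 <- fast_config(n = 2, seed = 11, days = 2, bouts_per_day = 0,
                      mislabel_rate = 0)
  log0 <- simulate_gps_log(generate_cohort(cfg0)[1, ], cfg0)
  expect_false(any(log0$activity == "WALKING"))

  # mislabel_rate = 1 -> zero Walking-labeled points
  cfg1 <- fast_config(n = 2, seed = 11, days = 2, mislabel_rate = 1,
                      vehicle_per_day = 0, still_per_day = 0)
  log1 <- simulate_gps_log(generate_cohort(cfg1)[1, ], cfg1)
  expect_gt(nrow(log1), 0)
  expect_false(any(log1$activity == "WALKING"))

  # noiseless walking: consecutive haversine speeds equal the true speed
  log <- simulate_gps_log(truths[1, ], cfg)
  expect_true(all(diff(log$t) > 0))
  walk <- log[log$activity == "WALKING", ]
  cl <- build_clusters(walk)
  for (one in cl) {
    sp <- compute_speeds(one)
    expect_true(all(abs(sp - truths$true_gait_speed[1]) < 1e-6))
  }

  # vehicle segments move faster than 2 m/s
  veh <- log[log$activity == "IN_VEHICLE", ]
  if (nrow(veh) >= 2) {
    vcl <- build_clusters(veh, min_points = 2)
    expect_true(all(unlist(lapply(vcl, compute_speeds)) > 2))
  }

  # unavailable gait stream or zero days -> empty log
  na_truth <- truths[2, ]; na_truth$gait_available <- FALSE
  expect_equal(nrow(simulate_gps_log(na_truth, cfg)), 0L)
  expect_equal(nrow(simulate_gps_log(
    truths[1, ], fast_config(n = 2, seed = 11, days = 0))), 0L)
})

test_that("pedometer output is a nonnegative diurnal count process", {
  cfg <- fast_config(n = 1, seed = 5, days = 200)
  truth <- generate_cohort(cfg)[1, ]
  truth$true_daily_steps <- 3000
  recs <- simulate_pedometer(truth, cfg)
  expect_true(all(recs$steps >= 0 & recs$steps == floor(recs$steps)))

  # daily totals average to the true level within 5%
  expect_lt(abs(daily_mean_steps(recs, cfg$tz_offset) - 3000) / 3000, 0.05)

  # overnight hours (local 22:00-05:59) carry no steps
  hour_of_day <- (floor((recs$t + cfg$tz_offset) / 3600)) %% 24
  expect_true(all(recs$steps[hour_of_day >= 22 | hour_of_day < 6] == 0))

  # degenerate cases
  expect_equal(nrow(simulate_pedometer(truth, fast_config(n = 1, days = 0))), 0L)
  truth0 <- truth; truth0$true_daily_steps <- 0
  expect_true(all(simulate_pedometer(truth0, cfg)$steps == 0))
})

test_that("chair-stand traces carry the planted cycle count for 30 s", {
  cfg <- fast_config(n = 1, seed = 6)
  truth <- generate_cohort(cfg)[1, ]
  tr <- simulate_sts_accel(truth, cfg)
  expect_equal(length(tr$az), 30 * cfg$accel_rate)
  expect_equal(count_sts_reps(tr), truth$true_sts_reps)

  truth0 <- truth; truth0$true_sts_reps <- 0
  expect_equal(count_sts_reps(simulate_sts_accel(truth0, cfg)), 0L)
})

test_that("self-reports stay on their ordinal supports and track the truth", {
  cfg <- fast_config(n = 300, seed = 8, days = 14)
  truths <- generate_cohort(cfg)
  all_reports <- do.call(rbind, lapply(seq_len(nrow(truths)), function(p)
    simulate_self_reports(truths[p, ], cfg)))
  rpe <- all_reports$rpe[!is.na(all_reports$rpe)]
  health <- all_reports$health[!is.na(all_reports$health)]
  expect_true(all(rpe >= 1 & rpe <= 15 & rpe == floor(rpe)))
  expect_true(all(health >= 1 & health <= 4 & health == floor(health)))

  # zero noise, full response -> every report equals the rounded true level
  cfg0 <- fast_config(n = 3, seed = 8, days = 5, rpe_noise_sd = 0,
                      health_noise_sd = 0, report_prob = 1)
  t0 <- generate_cohort(cfg0)
  r0 <- simulate_self_reports(t0[1, ], cfg0)
  expect_true(all(r0$rpe == round(t0$true_rpe_level[1])))
  expect_true(all(r0$health == round(t0$true_health_level[1])))
})

test_that("degenerate deficit registries force FI to the boundary", {
  reg <- fi_registry()
  zero_reg <- reg
  zero_reg$prev <- I(lapply(reg$levels, function(lv) {
    p <- rep(0, length(lv)); p[1] <- 1; p
  }))
  one_reg <- reg
  one_reg$prev <- I(lapply(reg$levels, function(lv) {
    p <- rep(0, length(lv)); p[length(lv)] <- 1; p
  }))
  zero_eff <- c(gait_speed = 0, sts_counts = 0, daily_steps = 0, rpe = 0,
                subjective_health = 0)
  zero_cov <- c(age = 0, sex = 0, height = 0, weight = 0, smm = 0,
                fat_pct = 0, sppb = 0)
  cfg0 <- fast_config(n = 5, seed = 2, registry = zero_reg, fi_item_noise = 1,
                      effect_map = zero_eff, covariate_effect_map = zero_cov)
  cfg1 <- fast_config(n = 5, seed = 2, registry = one_reg, fi_item_noise = 1,
                      effect_map = zero_eff, covariate_effect_map = zero_cov)
  fi0 <- rowMeans(simulate_deficit_matrix(generate_cohort(cfg0), cfg0))
  fi1 <- rowMeans(simulate_deficit_matrix(generate_cohort(cfg1), cfg1))
  expect_true(all(fi0 == 0))
  expect_true(all(fi1 == 1))
})
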