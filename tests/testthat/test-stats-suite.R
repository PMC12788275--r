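# Statistical suite: formula oracles (normal equations, RSS-based F-change,
# correlation-matrix VIFs), cross-checks against reference implementations,
# robustness and cross-validation behaviour.

test_that("Pearson correlation matches the closed-form oracle and cor.test", {
  x <- c(1.2, 2.7, 3.1, 4.8, 5.0, 6.3)
  y <- c(2.1, 2.0, 3.9, 4.1, 6.2, 5.8)
  res <- pearson_with_ci(x, y)

  # direct product-moment formula
  n <- 6
  r_oracle <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_lt(abs(res$r - r_oracle), 1e-12)

  ct <- cor.test(x, y)
  expect_equal(res$p, unname(ct$p.value), tolerance = 1e-10)
  expect_equal(res$ci, unname(ct$conf.int[1:2]), tolerance = 1e-6)

  expect_equal(pearson_with_ci(1:10, (1:10) * 2 + 3)$r, 1)
  # balanced orthogonal fixture
  xo <- c(-1, -1, 1, 1); yo <- c(-1, 1, -1, 1)
  expect_equal(pearson_with_ci(xo, yo)$r, 0)

  expect_error(pearson_with_ci(rep(1, 10), 1:10),
               class = "frailtylog_degenerate_input_error")
  expect_error(pearson_with_ci(1:3, 1:3), class = "frailtylog_input_error")
})

test_that("Fisher intervals cover a true r = -0.37 in 93-97% of samples", {
  set.seed(2024)
  n <- 94; rho <- -0.37
  hits <- 0
  for (i in 1:1000) {
    z <- rnorm(n)
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_with_ci(x, y)$ci
    if (ci[1] <= rho && rho <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 930)
  expect_lte(hits, 970)
})

test_that("OLS equals the normal-equations oracle to 1e-10", {
  fx <- reg_fixture(n = 30, k = 3, seed = 5)
  fit <- fit_linear_model(fx$y, fx$X)

  Xm <- cbind(1, as.matrix(fx$X))
  b_oracle <- solve(t(Xm) %*% Xm, t(Xm) %*% fx$y)
  expect_lt(max(abs(fit$coefficients$B - as.vector(b_oracle))), 1e-10)

  # exact linear data -> R^2 = 1 (lm warns about the perfect fit)
  y_exact <- as.matrix(fx$X) %*% c(1, -2, 0.5) + 3
  expect_equal(
    suppressWarnings(fit_linear_model(as.vector(y_exact), fx$X)$r_squared), 1)

  # independent noise at large n -> R^2 near 0
  set.seed(6)
  Xbig <- data.frame(x1 = rnorm(4000), x2 = rnorm(4000))
  expect_lt(fit_linear_model(rnorm(4000), Xbig)$r_squared, 0.01)

  # standardized slopes equal the z-scored refit
  zs <- function(v) (v - mean(v)) / sd(v)
  zfit <- lm(zs(fx$y) ~ zs(fx$X$x1) + zs(fx$X$x2) + zs(fx$X$x3))
  expect_equal(fit$coefficients$beta[-1], unname(coef(zfit)[-1]),
               tolerance = 1e-10)

  # rank deficiency is a collinearity error
  Xdef <- cbind(fx$X, x4 = fx$X$x1 + fx$X$x2)
  expect_error(fit_linear_model(fx$y, Xdef),
               class = "frailtylog_collinearity_error")
})

test_that("F-change equals the residual-sum oracle to 1e-10", {
  fx <- reg_fixture(n = 40, k = 5, seed = 7)
  X1 <- fx$X[, 1:2]; X2 <- fx$X[, 3:5]
  h <- hierarchical_fit(fx$y, X1, X2)

  rss <- function(X) sum(lm(fx$y ~ ., data = X)$residuals^2)
  rss1 <- rss(X1); rss2 <- rss(fx$X)
  f_oracle <- ((rss1 - rss2) / 3) / (rss2 / (40 - 5 - 1))
  expect_lt(abs(h$f_change$value - f_oracle), 1e-10)
  expect_equal(h$f_change$df1, 3)
  expect_equal(h$f_change$df2, 34)
  expect_gte(h$delta_r2, 0)
  expect_equal(h$delta_r2, h$step2$r_squared - h$step1$r_squared)

  # added predictors inside the step-1 span: dR^2 = 0, F-change = 0
  Xspan <- data.frame(s1 = X1$x1 + X1$x2, s2 = X1$x1 - 2 * X1$x2)
  h0 <- hierarchical_fit(fx$y, X1, Xspan)
  expect_lt(abs(h0$delta_r2), 1e-12)
  expect_equal(h0$f_change$value, 0)

  # y exactly linear in one added predictor -> step-2 R^2 = 1
  y_lin <- fx$X$x3 * 2 + 1
  expect_equal(
    suppressWarnings(hierarchical_fit(y_lin, X1, fx$X[, 3, drop = FALSE])$
                       step2$r_squared), 1)

  expect_error(hierarchical_fit(fx$y, X1[1:30, ], X2),
               class = "frailtylog_contract_error")
})

test_that("VIFs match the correlation-matrix oracle", {
  set.seed(8)
  # orthogonal centered predictors -> all VIF 1
  Xo <- data.frame(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(unname(vif(Xo)), c(1, 1))

  X <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
  X$V4 <- X$V1 + 0.5 * X$V2 + rnorm(200, 0, 0.4)
  v <- vif(X)
  # independent oracle: diagonal of the inverse correlation matrix
  expect_equal(unname(v), unname(diag(solve(cor(X)))), tolerance = 1e-10)
  expect_true(all(v >= 1))

  # near-duplicated predictor -> explosive VIF
  Xdup <- data.frame(a = rnorm(100))
  Xdup$b <- Xdup$a + rnorm(100, 0, 0.01)
  expect_gt(max(vif(Xdup)), 100)
})

test_that("Huber IRLS reproduces OLS without outliers and resists them", {
  # exact linear data: psi is linear, coefficients equal OLS
  fx <- reg_fixture(n = 50, k = 2, seed = 9, sigma = 0)
  hub <- huber_fit(fx$y, fx$X)
  ols <- suppressWarnings(fit_linear_model(fx$y, fx$X))
  expect_lt(max(abs(hub$coefficients$B - ols$coefficients$B)), 1e-8)
  expect_equal(hub$r_squared, 1, tolerance = 1e-10)

  # light-tailed noise: matches MASS::rlm (same psi, MAD scale) closely
  fx2 <- reg_fixture(n = 120, k = 3, seed = 10, sigma = 1)
  hub2 <- huber_fit(fx2$y, fx2$X)
  ref <- MASS::rlm(y ~ ., data = cbind(y = fx2$y, fx2$X), psi = MASS::psi.huber,
                   k = 1.345, scale.est = "MAD", maxit = 200)
  expect_lt(max(abs(hub2$coefficients$B - unname(coef(ref)))), 1e-4)

  # permutation invariance
  perm <- sample(120)
  hub2p <- huber_fit(fx2$y[perm], fx2$X[perm, ])
  expect_equal(hub2p$coefficients$B, hub2$coefficients$B, tolerance = 1e-8)

  # planted gross outliers: robust slope strictly closer to truth than OLS
  set.seed(11)
  n <- 100
  X <- data.frame(x = rnorm(n))
  y <- 2 * X$x + rnorm(n)
  bad <- sample(n, 5)
  y[bad] <- y[bad] + 10 * sd(y)
  hub3 <- huber_fit(y, X)
  ols3 <- fit_linear_model(y, X)
  expect_lt(abs(hub3$coefficients$B[2] - 2), abs(ols3$coefficients$B[2] - 2))
})

test_that("k-fold R^2 is seeded, exact on noiseless data, negative on noise", {
  fx <- reg_fixture(n = 60, k = 2, seed = 12, sigma = 0)
  cv <- kfold_r2(fx$y, fx$X, k = 5, seed = 3)
  expect_equal(cv$per_fold, rep(1, 5))

  cv_a <- kfold_r2(fx$y, fx$X, k = 5, seed = 3)
  expect_identical(cv, cv_a)
  fxn <- reg_fixture(n = 60, k = 2, seed = 12, sigma = 2)
  cv_b3 <- kfold_r2(fxn$y, fxn$X, k = 5, seed = 3)
  cv_b4 <- kfold_r2(fxn$y, fxn$X, k = 5, seed = 4)
  expect_false(identical(cv_b3$per_fold, cv_b4$per_fold))

  # y independent of X at n = 72: out-of-fold R^2 below zero in most seeds
  neg <- 0
  for (s in 1:100) {
    set.seed(s)
    yy <- rnorm(72)
    XX <- as.data.frame(matrix(rnorm(72 * 5), 72, 5))
    if (kfold_r2(yy, XX, k = 5, seed = s)$mean < 0) neg <- neg + 1
  }
  expect_gt(neg, 60)

  expect_error(kfold_r2(rnorm(8), data.frame(x = rnorm(8)), k = 5),
               class = "frailtylog_config_error")
})

test_that("complete-case assembly reports sizes and rejects empty results", {
  tbl <- data.frame(a = c(1, NA, 3, 4), b = c(1, 2, NA, 4), c = 1:4)
  cc <- assemble_complete_cases(tbl, c("a", "b"))
  expect_equal(nrow(cc), 2L)
  expect_equal(attr(cc, "n_before"), 4L)
  expect_equal(attr(cc, "n_after"), 2L)
  expect_identical(assemble_complete_cases(tbl, "c")$c, tbl$c)
  expect_error(assemble_complete_cases(tbl, "zzz"),
               class = "frailtylog_config_error")
  tbl$a <- NA_real_
  expect_error(assemble_complete_cases(tbl, c("a", "b")),
               class = "frailtylog_degenerate_sample_error")
})

test_that("sensitivity suite produces the 5 + 2 + 1 planned models", {
  set.seed(13)
  n <- 80
  tbl <- data.frame(fi = rnorm(n), age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    height = rnorm(n), weight = rnorm(n), smm = rnorm(n),
                    fat_pct = rnorm(n), sppb = rnorm(n),
                    gait_speed = rnorm(n), sts_counts = rnorm(n),
                    daily_steps = rnorm(n), rpe = rnorm(n),
                    subjective_health = rnorm(n))
  tbl$fi <- tbl$fi + 0.3 * tbl$gait_speed - 0.2 * tbl$sppb
  suite <- run_sensitivity_suite(tbl)
  expect_length(suite, 8L)
  expect_setequal(names(suite),
                  c("full", "drop_daily_steps", "drop_gait_speed",
                    paste0("single_", c("gait_speed", "sts_counts",
                                        "daily_steps", "rpe",
                                        "subjective_health"))))

  # sub-model R^2 never exceeds the full model's on the same sample
  full_r2 <- suite$full$step2$r_squared
  expect_lte(suite$drop_daily_steps$step2$r_squared, full_r2 + 1e-12)
  expect_lte(suite$drop_gait_speed$step2$r_squared, full_r2 + 1e-12)

  # single-predictor models equal a direct fit with that design
  direct <- fit_linear_model(
    tbl$fi, tbl[, c("age", "sex", "height", "weight", "smm", "fat_pct",
                    "sppb", "rpe")])
  expect_equal(suite$single_rpe$coefficients$B, direct$coefficients$B,
               tolerance = 1e-12)

  expect_error(run_sensitivity_suite(tbl, lifelogs = c("gait_speed", "nope")),
               class = "frailtylog_config_error")
})
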