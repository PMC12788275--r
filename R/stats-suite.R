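# Statistical suite: Pearson correlations with Fisher intervals,
# (hierarchical) OLS with standardized slopes and VIFs, Huber robust
# regression, k-fold cross-validated R-squared and the sensitivity plan.

#' Pearson correlation with p-value and Fisher confidence interval
#'
#' Product-moment correlation on complete pairs; two-sided p from the t
#' transform with n - 2 df; confidence interval from Fisher's z with
#' standard error 1/sqrt(n - 3).
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped.
#' @param conf Confidence level (default 0.95).
#' @return List of class `fl_corr`: `r`, `p`, `ci` (length 2), `n`.
#' @export
#' @examples
#' pearson_with_ci(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
pearson_with_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) fl_input_error("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) fl_input_error("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    fl_error("correlation undefined for constant input",
             "frailtylog_degenerate_input_error")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  zcrit <- qnorm(1 - (1 - conf) / 2)
  zr <- atanh(r)
  ci <- tanh(zr + c(-1, 1) * zcrit / sqrt(n - 3))
  structure(list(r = r, p = p, ci = ci, n = n), class = "fl_corr")
}

#' @export
print.fl_corr <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4g, 95%% CI [%.3f, %.3f], n = %d\n",
              x$r, x$p, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF of predictor j is 1 / (1 - R^2_j) where R^2_j comes from regressing
#' predictor j on all other predictors (with intercept). A single predictor
#' has VIF 1. Perfect collinearity yields Inf.
#'
#' @param X data.frame or matrix of predictors (n rows > k + 1).
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  k <- ncol(X)
  if (nrow(X) <= k + 1) fl_input_error("need n > k + 1 rows")
  if (k == 1L) return(setNames(1, names(X)))
  out <- vapply(seq_len(k), function(j) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[, -j, drop = FALSE]))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  setNames(out, names(X))
}

#' Ordinary least squares with standardized slopes
#'
#' Fits y on the predictor table with an intercept and reports raw slopes B
#' with standard errors, standardized slopes beta (z-scored outcome and
#' predictors), two-sided t tests with confidence intervals, the overall F
#' test, R^2 and per-predictor VIFs.
#'
#' @param y Numeric outcome.
#' @param X data.frame of numeric predictors (full column rank).
#' @param conf Confidence level for coefficient intervals.
#' @return List of class `fl_model_fit`: `coefficients` (data.frame with
#'   rows = intercept + predictors), `r_squared`, `f` (value, df1, df2, p),
#'   `n`, `sigma`, `vif`.
#' @export
fit_linear_model <- function(y, X, conf = 0.95) {
  X <- as.data.frame(X)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) fl_input_error("y and X must have the same rows")
  if (anyNA(y) || anyNA(X))
    fl_input_error("complete cases required; see assemble_complete_cases()")
  if (n <= k + 1) fl_input_error("need n > k + 1")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < k + 1)
    fl_error("predictor table is rank deficient",
             "frailtylog_collinearity_error")
  fit <- lm(y ~ ., data = X)
  sm <- summary(fit)
  cf <- sm$coefficients
  sds <- vapply(X, sd, 0)
  beta <- c(NA, cf[-1, 1] * sds / sd(y))
  tcrit <- qt(1 - (1 - conf) / 2, fit$df.residual)
  coefs <- data.frame(
    term = c("(Intercept)", names(X)),
    B = cf[, 1], SE = cf[, 2], beta = beta, t = cf[, 3], p = cf[, 4],
    ci_lo = cf[, 1] - tcrit * cf[, 2], ci_hi = cf[, 1] + tcrit * cf[, 2],
    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = coefs,
    r_squared = sm$r.squared,
    f = list(value = unname(fstat[1]), df1 = unname(fstat[2]),
             df2 = unname(fstat[3]),
             p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = n, sigma = sm$sigma,
    vif = if (k >= 1 && n > k + 1) vif(X) else NULL,
    residuals = unname(fit$residuals), fitted = unname(fit$fitted.values)
  ), class = "fl_model_fit")
}

#' @export
print.fl_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Linear model: n = %d, R^2 = %.3f, F(%g, %g) = %.2f, p = %.4g\n",
              x$n, x$r_squared, x$f$df1, x$f$df2, x$f$value, x$f$p))
  print(cbind(x$coefficients[, c("term", "B", "SE", "beta", "p")],
              VIF = c(NA, x$vif)), digits = digits)
  invisible(x)
}

#' Hierarchical regression with an R-squared-change F test
#'
#' Fits the step-1 model (y ~ X1) and the nested step-2 model
#' (y ~ X1 + X2_add) on the identical sample and tests the increment:
#' F_change = (dR^2 / dk) / ((1 - R2_2) / (n - k2 - 1)) on (dk, n - k2 - 1)
#' degrees of freedom.
#'
#' @param y Numeric outcome.
#' @param X1 data.frame of step-1 predictors.
#' @param X2_add data.frame of predictors added in step 2.
#' @return List of class `fl_hier_fit`: `step1`, `step2` (both
#'   `fl_model_fit`), `delta_r2`, `f_change` (value, df1, df2, p), `n`.
#' @export
hierarchical_fit <- function(y, X1, X2_add) {
  X1 <- as.data.frame(X1); X2_add <- as.data.frame(X2_add)
  if (nrow(X1) != length(y) || nrow(X2_add) != length(y))
    fl_error("step samples must contain identical rows",
             "frailtylog_contract_error")
  step1 <- fit_linear_model(y, X1)
  # Step-2 additions lying in the step-1 column span make the combined
  # design singular; R^2 is still well-defined and the increment is zero.
  step2 <- tryCatch(
    fit_linear_model(y, cbind(X1, X2_add)),
    frailtylog_collinearity_error = function(e) {
      fit <- lm(y ~ ., data = cbind(X1, X2_add))
      structure(list(coefficients = NULL,
                     r_squared = summary(fit)$r.squared,
                     f = NULL, n = length(y), sigma = summary(fit)$sigma,
                     vif = NULL, singular = TRUE),
                class = "fl_model_fit")
    })
  dk <- ncol(X2_add)
  k2 <- ncol(X1) + dk
  n <- length(y)
  delta <- step2$r_squared - step1$r_squared
  fch <- if (delta <= 0) 0 else
    (delta / dk) / ((1 - step2$r_squared) / (n - k2 - 1))
  structure(list(
    step1 = step1, step2 = step2, delta_r2 = delta,
    f_change = list(value = fch, df1 = dk, df2 = n - k2 - 1,
                    p = pf(fch, dk, n - k2 - 1, lower.tail = FALSE)),
    n = n
  ), class = "fl_hier_fit")
}

#' @export
print.fl_hier_fit <- function(x, ...) {
  cat(sprintf(paste0("Hierarchical regression (n = %d):\n",
                     "  Step 1 R^2 = %.3f; Step 2 R^2 = %.3f\n",
                     "  dR^2 = %.3f, F-change(%d, %d) = %.2f, p = %.4g\n"),
              x$n, x$step1$r_squared, x$step2$r_squared, x$delta_r2,
              x$f_change$df1, x$f_change$df2, x$f_change$value, x$f_change$p))
  invisible(x)
}

# Huber psi weight: 1 inside the threshold, c/|u| outside.
huber_weights <- function(u, c) pmin(1, c / pmax(abs(u), .Machine$double.eps))

#' Huber robust regression (IRLS M-estimation)
#'
#' Iteratively reweighted least squares with Huber's weight function
#' (tuning constant 1.345 by default) and scale re-estimated each iteration
#' by the median absolute deviation of the residuals. Reports a robust
#' "R-squared" as the squared correlation between fitted and observed
#' values, and a Wald chi-squared test that all slopes are jointly zero.
#' With no outliers (residuals inside the linear region of the psi
#' function) the estimate coincides with OLS.
#'
#' @param y Numeric outcome.
#' @param X data.frame of predictors.
#' @param tuning Huber tuning constant (in robust-scale units).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return List of class `fl_huber_fit`: `coefficients` (term, B, SE, p),
#'   `r_squared`, `chi_sq` (value, df, p), `scale`, `iterations`, `n`.
#' @export
huber_fit <- function(y, X, tuning = 1.345, max_iter = 500, tol = 1e-8) {
  X <- as.data.frame(X)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) fl_input_error("need n > k + 1")
  if (anyNA(y) || anyNA(X)) fl_input_error("complete cases required")
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  b <- qr.solve(Xm, y)
  converged <- FALSE
  s <- 0
  for (it in seq_len(max_iter)) {
    r <- y - Xm %*% b
    s <- median(abs(r)) / 0.6745   # regression MAD, centered at zero
    if (s < 1e-10) { converged <- TRUE; break }  # (near-)exact fit
    w <- huber_weights(r / s, tuning)
    b_new <- qr.solve(Xm * sqrt(as.vector(w)), sqrt(as.vector(w)) * y)
    if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
      b <- b_new; converged <- TRUE; break
    }
    b <- b_new
  }
  if (!converged)
    fl_error(sprintf("IRLS did not converge in %d iterations", max_iter),
             "frailtylog_convergence_error")
  r <- as.vector(y - Xm %*% b)
  fitted <- as.vector(Xm %*% b)
  # asymptotic covariance of the Huber M-estimator (pseudo-observation form)
  if (s > 1e-10) {
    u <- r / s
    psi <- pmax(pmin(u, tuning), -tuning)
    mpsi_prime <- mean(abs(u) <= tuning)
    vcov_b <- (s^2 * sum(psi^2) / (n - k - 1)) / mpsi_prime^2 *
      solve(crossprod(Xm))
    se <- sqrt(diag(vcov_b))
    zstat <- as.vector(b) / se
    pvals <- 2 * pnorm(-abs(zstat))
    bs <- as.vector(b)[-1]
    chi <- as.numeric(t(bs) %*% solve(vcov_b[-1, -1, drop = FALSE]) %*% bs)
  } else {
    se <- rep(0, k + 1); pvals <- rep(0, k + 1); chi <- Inf
  }
  structure(list(
    coefficients = data.frame(term = colnames(Xm), B = as.vector(b), SE = se,
                              p = pvals, row.names = NULL,
                              stringsAsFactors = FALSE),
    r_squared = if (sd(fitted) > 0) cor(fitted, y)^2 else 0,
    chi_sq = list(value = chi, df = k,
                  p = pchisq(chi, k, lower.tail = FALSE)),
    scale = s, iterations = it, n = n, fitted = fitted, residuals = r
  ), class = "fl_huber_fit")
}

#' @export
print.fl_huber_fit <- function(x, ...) {
  cat(sprintf(
    "Huber robust regression: n = %d, R^2 = %.3f, chi^2(%d) = %.2f, p = %.4g\n",
    x$n, x$r_squared, x$chi_sq$df, x$chi_sq$value, x$chi_sq$p))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' k-fold cross-validated out-of-sample R-squared
#'
#' Shuffles rows into k folds (seeded), fits OLS on k-1 folds and scores
#' 1 - SS_res / SS_tot on the held-out fold, SS_tot taken about the held-out
#' mean. Out-of-fold R-squared can be negative when the model predicts worse
#' than the held-out mean.
#'
#' @param y Numeric outcome.
#' @param X data.frame of predictors.
#' @param k Number of folds.
#' @param seed Integer seed for the fold shuffle.
#' @return List: `mean`, `sd`, `per_fold` (length k), `k`, `seed`.
#' @export
kfold_r2 <- function(y, X, k = 5, seed = 1) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n < 2 * k) fl_config_error("need n >= 2k rows")
  if (anyNA(y) || anyNA(X)) fl_input_error("complete cases required")
  fold <- with_stream_seed(seed, sample(rep_len(seq_len(k), n)))
  if (min(table(fold)) < 2) fl_config_error("every fold needs >= 2 rows")
  per_fold <- vapply(seq_len(k), function(f) {
    test <- fold == f
    fit <- lm(y ~ ., data = cbind(y = y[!test], X[!test, , drop = FALSE]))
    pred <- predict(fit, newdata = X[test, , drop = FALSE])
    ss_res <- sum((y[test] - pred)^2)
    ss_tot <- sum((y[test] - mean(y[test]))^2)
    1 - ss_res / ss_tot
  }, 0)
  list(mean = mean(per_fold), sd = sd(per_fold), per_fold = per_fold,
       k = k, seed = seed)
}

#' Restrict a table to complete cases on named variables
#'
#' Listwise deletion: removes every row with a missing value among the named
#' variables and records the sample sizes before and after as attributes
#' `n_before` / `n_after`.
#'
#' @param tbl data.frame.
#' @param variables Character vector of column names.
#' @return The filtered data.frame.
#' @export
assemble_complete_cases <- function(tbl, variables) {
  missing_vars <- setdiff(variables, names(tbl))
  if (length(missing_vars))
    fl_config_error(paste("unknown variables:",
                          paste(missing_vars, collapse = ", ")))
  keep <- complete.cases(tbl[, variables, drop = FALSE])
  if (!any(keep))
    fl_error("no complete cases remain", "frailtylog_degenerate_sample_error")
  out <- tbl[keep, , drop = FALSE]
  attr(out, "n_before") <- nrow(tbl)
  attr(out, "n_after") <- sum(keep)
  out
}

#' Sensitivity-analysis model suite
#'
#' Reproduces the robustness plan around the hierarchical model: the full
#' covariates-plus-lifelogs hierarchy, the hierarchy re-estimated without
#' daily mean steps and without gait speed, and one model per lifelog
#' variable entered alone alongside the covariates. Each model is fitted on
#' its own complete-case sample.
#'
#' @param tbl Per-participant analysis table.
#' @param outcome Outcome column name (the FI).
#' @param covariates Covariate column names (step 1).
#' @param lifelogs Lifelog column names (step 2 additions).
#' @return Named list: `full` (`fl_hier_fit`), `drop_<var>` hierarchies for
#'   daily steps and gait speed, and `single_<var>` fits (`fl_model_fit`).
#' @export
run_sensitivity_suite <- function(tbl, outcome = "fi",
                                  covariates = c("age", "sex", "height",
                                                 "weight", "smm", "fat_pct",
                                                 "sppb"),
                                  lifelogs = c("gait_speed", "sts_counts",
                                               "daily_steps", "rpe",
                                               "subjective_health")) {
  unknown <- setdiff(c(outcome, covariates, lifelogs), names(tbl))
  if (length(unknown))
    fl_config_error(paste("unknown variables:",
                          paste(unknown, collapse = ", ")))
  hier <- function(lls) {
    cc <- assemble_complete_cases(tbl, c(outcome, covariates, lls))
    hierarchical_fit(cc[[outcome]], cc[, covariates, drop = FALSE],
                     cc[, lls, drop = FALSE])
  }
  out <- list(full = hier(lifelogs))
  for (drop_var in intersect(c("daily_steps", "gait_speed"), lifelogs))
    out[[paste0("drop_", drop_var)]] <- hier(setdiff(lifelogs, drop_var))
  for (v in lifelogs) {
    cc <- assemble_complete_cases(tbl, c(outcome, covariates, v))
    out[[paste0("single_", v)]] <-
      fit_linear_model(cc[[outcome]], cc[, c(covariates, v), drop = FALSE])
  }
  out
}
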