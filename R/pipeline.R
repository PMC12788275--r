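# End-to-end orchestration: simulate -> extract features -> score FI ->
# analyze -> report, plus the CSV interchange formats.

#' Build the per-participant feature table from simulated raw streams
#'
#' For every participant: simulates the labeled GPS log and runs the full
#' gait-speed pipeline, counts chair-stand repetitions from the simulated
#' accelerometer trace, aggregates pedometer records into daily and hourly
#' mean steps, averages the self-reports, scores the deficit profile into
#' the Frailty Index, and merges the clinical covariates. This is the single
#' merged table consumed by the statistical suite (one row per participant).
#'
#' @param truths A [generate_cohort()] data.frame.
#' @param config The matching [cohort_config()].
#' @param mask Optional environment mask for the gait pipeline.
#' @return data.frame with id, the six lifelog features (`gait_speed`,
#'   `sts_counts`, `daily_steps`, `hourly_steps`, `rpe`,
#'   `subjective_health`), `fi`, and the covariates.
#' @export
build_feature_table <- function(truths, config, mask = NULL) {
  deficits <- simulate_deficit_matrix(truths, config)
  n <- nrow(truths)
  feat <- data.frame(
    id = truths$id,
    gait_speed = rep(NA_real_, n), sts_counts = rep(NA_real_, n),
    daily_steps = rep(NA_real_, n), hourly_steps = rep(NA_real_, n),
    rpe = rep(NA_real_, n), subjective_health = rep(NA_real_, n),
    fi = rep(NA_real_, n), stringsAsFactors = FALSE)
  for (p in seq_len(n)) {
    truth <- truths[p, ]
    gait <- gait_speed_pipeline(simulate_gps_log(truth, config), mask = mask)
    feat$gait_speed[p] <- gait$usual_gait_speed
    feat$sts_counts[p] <- count_sts_reps(simulate_sts_accel(truth, config))
    steps <- simulate_pedometer(truth, config)
    if (nrow(steps)) {
      feat$daily_steps[p] <- daily_mean_steps(steps, config$tz_offset)
      feat$hourly_steps[p] <- hourly_mean_steps(steps, config$tz_offset)
    }
    reports <- simulate_self_reports(truth, config)
    feat$rpe[p] <- aggregate_rpe(reports$rpe)
    feat$subjective_health[p] <- aggregate_subjective_health(reports$health)
    feat$fi[p] <- compute_fi(deficits[p, ])$fi
  }
  cbind(feat, truths[, c("age", "sex", "height", "weight", "smm", "fat_pct",
                         "sppb"), drop = FALSE])
}

FEATURE_LABELS <- c(
  gait_speed = "Usual gait speed (m/s)", sts_counts = "30 s STS counts",
  daily_steps = "Daily mean steps", hourly_steps = "Hourly mean steps",
  rpe = "RPE", subjective_health = "Subjective health status")

#' Correlate the Frailty Index with every lifelog feature
#'
#' Pearson correlation of the FI with each of the six lifelog features on
#' pairwise-complete participants, with Fisher confidence intervals.
#'
#' @param tbl Feature table from [build_feature_table()].
#' @return data.frame with one row per feature: `feature`, `n`, `r`, `p`,
#'   `ci_lo`, `ci_hi`.
#' @export
correlate_features <- function(tbl) {
  feats <- names(FEATURE_LABELS)
  rows <- lapply(feats, function(f) {
    res <- pearson_with_ci(tbl[[f]], tbl$fi)
    data.frame(feature = f, n = res$n, r = res$r, p = res$p,
               ci_lo = res$ci[1], ci_hi = res$ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort, builds the feature table, and runs the
#' complete statistical plan: FI-lifelog correlations, the hierarchical
#' covariates-then-lifelogs regression (hourly steps excluded from the
#' model per the correlation screen design), the lifelog-only model with its
#' Huber robust re-fit and 5-fold cross-validated R-squared, and the
#' sensitivity suite. Writes CSV artifacts and a provenance log when
#' `out_dir` is given. Deterministic given (config, seed).
#'
#' @param config A [cohort_config()]; unknown entries are rejected there.
#' @param out_dir Optional output directory for CSV artifacts.
#' @param mask Optional environment mask.
#' @return List of class `fl_run`: `features`, `correlations`,
#'   `hierarchical`, `lifelog_only`, `huber`, `cv`, `sensitivity`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, mask = NULL) {
  truths <- generate_cohort(config)
  features <- build_feature_table(truths, config, mask = mask)
  correlations <- correlate_features(features)

  covariates <- c("age", "sex", "height", "weight", "smm", "fat_pct", "sppb")
  lifelogs <- c("gait_speed", "sts_counts", "daily_steps", "rpe",
                "subjective_health")
  cc <- assemble_complete_cases(features, c("fi", covariates, lifelogs))
  hierarchical <- hierarchical_fit(cc$fi, cc[, covariates],
                                   cc[, lifelogs])
  cc_ll <- assemble_complete_cases(features, c("fi", lifelogs))
  lifelog_only <- fit_linear_model(cc_ll$fi, cc_ll[, lifelogs])
  huber <- huber_fit(cc_ll$fi, cc_ll[, lifelogs])
  cv <- kfold_r2(cc_ll$fi, cc_ll[, lifelogs], k = 5, seed = config$seed)
  sensitivity <- run_sensitivity_suite(features, "fi", covariates, lifelogs)

  log <- list(
    seed = config$seed,
    n_participants = config$n_participants,
    n_features_rows = nrow(features),
    n_complete_hierarchical = attr(cc, "n_after"),
    n_complete_lifelog_only = attr(cc_ll, "n_after"),
    feature_availability = colSums(!is.na(
      features[, names(FEATURE_LABELS)])),
    package_version = as.character(utils::packageVersion("frailtylog")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- structure(list(features = features, correlations = correlations,
                        hierarchical = hierarchical,
                        lifelog_only = lifelog_only, huber = huber, cv = cv,
                        sensitivity = sensitivity, log = log),
                   class = "fl_run")
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(run$features, "features.csv")
  wr(run$correlations, "correlations.csv")
  wr(run$hierarchical$step2$coefficients, "hierarchical_step2.csv")
  wr(run$lifelog_only$coefficients, "lifelog_only.csv")
  writeLines(render_tables(run), file.path(out_dir, "report.txt"))
  writeLines(jsonlite::toJSON(run$log, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_log.json"))
  invisible(out_dir)
}

sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, " ***",
                              ifelse(p < 0.01, " **",
                                     ifelse(p < 0.05, " *", ""))))
}

#' Render the analysis results as a plain-text report
#'
#' Emits the correlation, hierarchical-regression, lifelog-only, robust,
#' cross-validation and sensitivity tables with sample sizes, estimates,
#' confidence intervals, p-values (starred at 0.05 / 0.01 / 0.001) and
#' VIFs. Rendering is a pure function of the results: regenerating the
#' report yields identical text.
#'
#' @param run An `fl_run` from [run_pipeline()], or a partial results list.
#' @return Character vector of report lines.
#' @export
render_tables <- function(run) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))

  add("== FI x digital lifelog correlations ==")
  add("%-28s %5s %8s %10s %18s", "Feature", "n", "r", "p", "95% CI")
  if (!is.null(run$correlations) && nrow(run$correlations)) {
    for (i in seq_len(nrow(run$correlations))) {
      co <- run$correlations[i, ]
      add("%-28s %5d %8.3f%s %9.3g [%6.3f, %6.3f]",
          FEATURE_LABELS[[co$feature]], co$n, co$r, sig_stars(co$p), co$p,
          co$ci_lo, co$ci_hi)
    }
  }

  coef_block <- function(fit) {
    add("%-22s %10s %9s %8s %9s %7s", "Term", "B", "SE", "beta", "p", "VIF")
    cf <- fit$coefficients
    vifs <- c(NA, fit$vif)
    for (i in seq_len(nrow(cf))) {
      add("%-22s %10.4f %9.4f %8s %8.3g%s %7s", cf$term[i], cf$B[i],
          cf$SE[i],
          ifelse(is.na(cf$beta[i]), "", sprintf("%.3f", cf$beta[i])),
          cf$p[i], sig_stars(cf$p[i]),
          ifelse(is.na(vifs[i]), "", sprintf("%.3f", vifs[i])))
    }
  }

  if (!is.null(run$hierarchical)) {
    h <- run$hierarchical
    add("")
    add("== Hierarchical regression (FI ~ covariates, + lifelogs) ==")
    add("Step 1: R^2 = %.3f, F(%g, %g) = %.2f%s", h$step1$r_squared,
        h$step1$f$df1, h$step1$f$df2, h$step1$f$value, sig_stars(h$step1$f$p))
    add("Step 2: R^2 = %.3f, F(%g, %g) = %.2f%s", h$step2$r_squared,
        h$step2$f$df1, h$step2$f$df2, h$step2$f$value, sig_stars(h$step2$f$p))
    add("dR^2 = %.3f, F-change(%d, %d) = %.2f%s", h$delta_r2,
        h$f_change$df1, h$f_change$df2, h$f_change$value,
        sig_stars(h$f_change$p))
    coef_block(h$step2)
  }

  if (!is.null(run$lifelog_only)) {
    add("")
    add("== Lifelog-only model ==")
    add("R^2 = %.3f, F(%g, %g) = %.2f%s, n = %d",
        run$lifelog_only$r_squared, run$lifelog_only$f$df1,
        run$lifelog_only$f$df2, run$lifelog_only$f$value,
        sig_stars(run$lifelog_only$f$p), run$lifelog_only$n)
    coef_block(run$lifelog_only)
  }

  if (!is.null(run$huber)) {
    add("")
    add("== Huber robust re-fit of the lifelog-only model ==")
    add("Robust R^2 = %.3f, chi^2(%d) = %.2f%s", run$huber$r_squared,
        run$huber$chi_sq$df, run$huber$chi_sq$value,
        sig_stars(run$huber$chi_sq$p))
  }

  if (!is.null(run$cv)) {
    add("")
    add("== 5-fold cross-validation of the lifelog-only model ==")
    add("Out-of-fold R^2 = %.4f (SD = %.3f)", run$cv$mean, run$cv$sd)
  }

  if (!is.null(run$sensitivity)) {
    add("")
    add("== Sensitivity models ==")
    for (nm in names(run$sensitivity)) {
      m <- run$sensitivity[[nm]]
      if (inherits(m, "fl_hier_fit")) {
        add("%-28s R^2 = %.3f, F(%g, %g) = %.2f%s, n = %d", nm,
            m$step2$r_squared, m$step2$f$df1, m$step2$f$df2, m$step2$f$value,
            sig_stars(m$step2$f$p), m$n)
      } else {
        add("%-28s R^2 = %.3f, F(%g, %g) = %.2f%s, n = %d", nm,
            m$r_squared, m$f$df1, m$f$df2, m$f$value, sig_stars(m$f$p), m$n)
      }
    }
  }
  lines
}

#' @export
print.fl_run <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}

# ---- CSV interchange -------------------------------------------------------

#' Write the raw simulated streams of a cohort to CSV files
#'
#' Emits the CSV dialects the analysis functions read: `gps.csv`
#' (`participant_id, timestamp_iso8601_utc, lat, lon, activity`),
#' `steps.csv` (`participant_id, timestamp_iso8601_utc, steps`),
#' `accel.csv` (`participant_id, t_s, az_ms2`), `reports.csv`
#' (`participant_id, date, rpe, health`), `deficits.csv` (one row per
#' participant, one column per registry item) and `truths.csv`.
#'
#' @param truths A [generate_cohort()] data.frame.
#' @param config The matching [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_csv <- function(truths, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  iso <- function(t) format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                            "%Y-%m-%dT%H:%M:%SZ")
  gps <- list(); steps <- list(); accel <- list(); reports <- list()
  for (p in seq_len(nrow(truths))) {
    truth <- truths[p, ]
    g <- simulate_gps_log(truth, config)
    if (nrow(g)) gps[[p]] <- data.frame(
      participant_id = truth$id, timestamp_iso8601_utc = iso(g$t),
      lat = g$lat, lon = g$lon, activity = g$activity)
    s <- simulate_pedometer(truth, config)
    if (nrow(s)) steps[[p]] <- data.frame(
      participant_id = truth$id, timestamp_iso8601_utc = iso(s$t),
      steps = s$steps)
    a <- simulate_sts_accel(truth, config)
    if (!is.null(a)) accel[[p]] <- data.frame(
      participant_id = truth$id, t_s = a$t, az_ms2 = a$az)
    r <- simulate_self_reports(truth, config)
    if (nrow(r)) reports[[p]] <- cbind(participant_id = truth$id, r)
  }
  wr <- function(lst, name, header) {
    df <- do.call(rbind, lst)
    if (is.null(df)) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                   header))
    }
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(gps, "gps.csv", c("participant_id", "timestamp_iso8601_utc", "lat",
                       "lon", "activity"))
  wr(steps, "steps.csv", c("participant_id", "timestamp_iso8601_utc",
                           "steps"))
  wr(accel, "accel.csv", c("participant_id", "t_s", "az_ms2"))
  wr(reports, "reports.csv", c("participant_id", "day", "date", "rpe",
                               "health"))
  write.csv(cbind(participant_id = truths$id,
                  as.data.frame(simulate_deficit_matrix(truths, config))),
            file.path(out_dir, "deficits.csv"), row.names = FALSE)
  write.csv(as.data.frame(truths), file.path(out_dir, "truths.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' Build a cohort configuration from a key-value file
#'
#' Reads a flat YAML or JSON file of [cohort_config()] arguments. Unknown
#' keys are rejected rather than silently ignored, so a typo in a config
#' file cannot leave a default in place unnoticed.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top-level keys
#'   are `cohort_config()` argument names; map-valued entries
#'   (`effect_map`, `missingness_map`, `covariate_effect_map`) become named
#'   vectors.
#' @return A validated `fl_cohort_config`.
#' @export
cohort_config_from_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      fl_config_error("the yaml package is required to read YAML configs")
    raw <- yaml::read_yaml(path)
  } else {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    fl_config_error(paste("unknown config keys:",
                          paste(unknown, collapse = ", ")))
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  do.call(cohort_config, raw)
}

#' Read a labeled GPS log from CSV
#'
#' Expects columns `participant_id, timestamp_iso8601_utc, lat, lon,
#' activity` and returns the internal log layout (`t, lat, lon, activity`)
#' for one or all participants.
#'
#' @param path CSV path.
#' @param participant Optional participant id filter.
#' @return data.frame (with a `participant_id` column when unfiltered).
#' @export
read_gps_csv <- function(path, participant = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$t <- as.numeric(as.POSIXct(df$timestamp_iso8601_utc,
                                format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  out <- df[, c("participant_id", "t", "lat", "lon", "activity")]
  if (!is.null(participant)) {
    out <- out[out$participant_id == participant,
               c("t", "lat", "lon", "activity"), drop = FALSE]
  }
  out[order(out$t), , drop = FALSE]
}
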