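# Deficit-accumulation Frailty Index: item registry, raw-measure mappers and
# the normalized score with missing-item denominator adjustment.

#' Default 50-item deficit registry
#'
#' Returns the default item registry used for Frailty Index scoring and by the
#' synthetic deficit generator. The registry reconstructs a 50-item
#' comprehensive-geriatric-assessment FI: 21 chronic conditions, 6 ADL (Katz)
#' items, 8 IADL (Lawton-Brody) items, 4 Nagi disablement items, 3
#' Rosow-Breslau mobility items, significant weight loss, low BMI, low
#' skeletal muscle mass, the Mini-Cog cognitive screen (graded), gait speed
#' (graded), chair-stand time (graded), handgrip strength and balance
#' (graded).
#'
#' Each item carries the admissible deficit `levels` (a subset of \[0, 1\],
#' ordered from least to most frail) and `prev`, the marginal probability of
#' each level used by the synthetic generator. Binary items have levels
#' `c(0, 1)`. Marginal prevalences are chosen so that the implied mean FI is
#' about 0.091 in a community-dwelling cohort of older adults, with domain
#' frequencies in line with published cohorts of this population.
#'
#' @return A data.frame with one row per item and columns `name`, `domain`,
#'   `kind` (`"binary"`, `"graded"` or `"threshold"`), and list-columns
#'   `levels` and `prev`.
#' @export
#' @examples
#' reg <- fi_registry()
#' nrow(reg) # 50
#' table(reg$domain)
fi_registry <- function() {
  item <- function(name, domain, kind, levels, prev) {
    stopifnot(abs(sum(prev) - 1) < 1e-9, length(levels) == length(prev))
    data.frame(name = name, domain = domain, kind = kind,
               levels = I(list(levels)), prev = I(list(prev)))
  }
  bin <- function(name, domain, p, kind = "binary")
    item(name, domain, kind, c(0, 1), c(1 - p, p))

  rows <- list()
  for (i in 1:21) rows <- c(rows, list(
    bin(sprintf("condition_%02d", i), "conditions", 0.110)))
  for (i in 1:6) rows <- c(rows, list(
    bin(sprintf("adl_%02d", i), "adl", 0.018)))
  for (i in 1:8) rows <- c(rows, list(
    bin(sprintf("iadl_%02d", i), "iadl", 0.009)))
  for (i in 1:4) rows <- c(rows, list(
    bin(sprintf("nagi_%02d", i), "nagi", 0.093)))
  for (i in 1:3) rows <- c(rows, list(
    bin(sprintf("rosow_%02d", i), "rosow", 0.050)))
  rows <- c(rows, list(
    bin("weight_loss", "anthropometry", 0.090, kind = "threshold"),
    bin("low_bmi", "anthropometry", 0.033, kind = "threshold"),
    bin("low_smm", "anthropometry", 0.200, kind = "threshold"),
    item("mini_cog", "cognition", "graded",
         c(0, 0.3, 0.7, 1), c(0.45, 0.35, 0.19, 0.01)),
    item("slow_gait", "performance", "graded",
         c(0, 0.5, 1), c(0.512, 0.381, 0.107)),
    item("chair_stand", "performance", "graded",
         c(0, 0.5, 1), c(0.60, 0.30, 0.10)),
    bin("low_grip", "performance", 0.250, kind = "threshold"),
    item("balance", "performance", "graded",
         c(0, 0.5, 1), c(0.75, 0.15, 0.10))
  ))
  do.call(rbind, rows)
}

#' Convert a Mini-Cog score to a deficit value
#'
#' Maps the 0-5 Mini-Cog cognitive screen onto the frailty deficit scale:
#' a score of 5 maps to 0 deficit points, 4 to 0.3, scores 1-3 to 0.7, and 0
#' to 1.
#'
#' @param score Integer vector with values in 0..5.
#' @return Numeric vector of deficit values in \[0, 1\].
#' @export
#' @examples
#' map_mini_cog(c(5, 4, 2, 0)) # 0.0 0.3 0.7 1.0
map_mini_cog <- function(score) {
  if (length(score) == 0L) return(numeric(0))
  if (!is.numeric(score)) fl_validation_error("Mini-Cog score must be numeric")
  bad <- !is.na(score) & (score != floor(score) | score < 0 | score > 5)
  if (any(bad)) fl_validation_error("Mini-Cog score must be an integer in 0..5")
  lut <- c(`0` = 1, `1` = 0.7, `2` = 0.7, `3` = 0.7, `4` = 0.3, `5` = 0)
  unname(lut[as.character(score)])
}

#' Score threshold-type deficit items
#'
#' Applies the fixed-cutoff deficit rules: weight loss of more than 4.5 kg in
#' the past year, body-mass index at or below 18.5 kg/m^2, handgrip strength
#' below a sex-specific cutoff, and skeletal muscle mass below a cutoff
#' (either explicit or the sex-specific lowest quintile of the supplied
#' cohort).
#'
#' @param measures data.frame with columns `weight_loss_kg`, `bmi`, `grip_kg`,
#'   `smm_kg` and `sex` (`"F"`/`"M"` or 1 = female / 0 = male). Missing
#'   measures yield missing deficits.
#' @param grip_cutoffs Named vector `c(M = , F = )` in kg; grip strictly below
#'   the cutoff scores 1.
#' @param smm_cutoffs Either a named vector `c(M = , F = )` in kg, or `NULL`
#'   to use the sex-specific 20th percentile of `measures$smm_kg`.
#' @return data.frame with columns `weight_loss`, `low_bmi`, `low_grip`,
#'   `low_smm`, each 0/1 (or NA where the raw measure is missing).
#' @export
map_threshold_items <- function(measures,
                                grip_cutoffs = c(M = 28, F = 18),
                                smm_cutoffs = NULL) {
  need <- c("weight_loss_kg", "bmi", "grip_kg", "smm_kg", "sex")
  miss <- setdiff(need, names(measures))
  if (length(miss))
    fl_validation_error(paste("missing columns:", paste(miss, collapse = ", ")))
  sex <- measures$sex
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "F", "M")
  sex <- toupper(as.character(sex))
  if (any(is.na(sex)))
    fl_validation_error("sex is required for sex-specific deficit items")
  if (!all(sex %in% c("F", "M")))
    fl_validation_error("sex must be coded F/M or 1 (female)/0 (male)")
  if (is.null(smm_cutoffs)) {
    smm_cutoffs <- c(
      M = unname(quantile(measures$smm_kg[sex == "M"], 0.2, na.rm = TRUE)),
      F = unname(quantile(measures$smm_kg[sex == "F"], 0.2, na.rm = TRUE)))
  }
  data.frame(
    weight_loss = as.numeric(measures$weight_loss_kg > 4.5),
    low_bmi = as.numeric(measures$bmi <= 18.5),
    low_grip = as.numeric(measures$grip_kg < grip_cutoffs[sex]),
    low_smm = as.numeric(measures$smm_kg < smm_cutoffs[sex])
  )
}

#' Score a graded performance measure against ordered cutpoints
#'
#' Assigns the deficit level of the interval containing the measure. With
#' `direction = "higher_better"` (e.g. gait speed) measures at or above the
#' best cutpoint score the least-frail level; with `"lower_better"` (e.g.
#' chair-stand completion time) the ordering is reversed. A measure exactly on
#' a cutpoint is assigned to the less-frail side.
#'
#' @param x Numeric vector of raw measures.
#' @param cutpoints Strictly increasing numeric cutpoints (length m).
#' @param levels Deficit levels (length m + 1) ordered from the least-frail to
#'   the most-frail interval.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return Numeric vector of deficit values; NA propagates.
#' @export
#' @examples
#' # gait speed: >= 1.0 m/s -> 0, 0.6-1.0 -> 0.5, < 0.6 -> 1
#' map_graded_performance(c(1.3, 1.0, 0.8, 0.5), c(0.6, 1.0), c(0, 0.5, 1))
map_graded_performance <- function(x, cutpoints, levels,
                                   direction = c("higher_better",
                                                 "lower_better")) {
  direction <- match.arg(direction)
  if (is.unsorted(cutpoints, strictly = TRUE))
    fl_config_error("cutpoints must be strictly increasing")
  if (length(levels) != length(cutpoints) + 1L)
    fl_config_error("need exactly one more level than cutpoints")
  if (is.unsorted(levels))
    fl_config_error("deficit levels must be nondecreasing in severity")
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (direction == "higher_better") {
    # ties count toward the better (less frail) side of the cutpoint
    idx <- length(cutpoints) - findInterval(x[ok], cutpoints, left.open = FALSE)
  } else {
    idx <- findInterval(x[ok], cutpoints, left.open = TRUE)
  }
  out[ok] <- levels[idx + 1L]
  out
}

#' Compute the normalized Frailty Index
#'
#' FI is the sum of non-missing deficit values divided by the number of
#' non-missing items, so that missing deficits shrink the denominator rather
#' than counting as zero. With a fully observed default registry the
#' denominator is the registry size (50).
#'
#' @param values Numeric vector of per-item deficit values in \[0, 1\], with
#'   NA marking missing items. Its length defines the registry size.
#' @return List of class `fl_fi` with elements `fi`, `n_present`, `n_missing`.
#' @export
#' @examples
#' compute_fi(c(rep(1, 8), rep(0, 32), rep(NA, 10)))$fi # 0.2
compute_fi <- function(values) {
  if (!is.numeric(values)) fl_validation_error("deficit values must be numeric")
  present <- !is.na(values)
  if (!any(present)) fl_error("all deficit items missing; FI undefined",
                              "frailtylog_undefined_fi_error")
  v <- values[present]
  if (any(v < 0 | v > 1))
    fl_validation_error("deficit values must lie in [0, 1]")
  structure(list(fi = sum(v) / sum(present),
                 n_present = sum(present),
                 n_missing = sum(!present)),
            class = "fl_fi")
}

#' @export
print.fl_fi <- function(x, ...) {
  cat(sprintf("Frailty Index: %.4f (%d items scored, %d missing)\n",
              x$fi, x$n_present, x$n_missing))
  invisible(x)
}

#' Default grading cutpoints for performance items
#'
#' Gait speed (m/s, higher better): at or above 1.0 scores 0, 0.6 to 1.0
#' scores 0.5, below 0.6 scores 1. Chair-stand time (s, lower better) and
#' tandem balance hold (s, higher better) follow short-physical-performance
#' -battery style bands. All cutpoints are configuration, not fixed science.
#'
#' @return Named list of grading specifications.
#' @export
fi_default_gradings <- function() {
  list(
    slow_gait = list(cutpoints = c(0.6, 1.0), levels = c(0, 0.5, 1),
                     direction = "higher_better"),
    chair_stand = list(cutpoints = c(11.2, 16.7), levels = c(0, 0.5, 1),
                       direction = "lower_better"),
    balance = list(cutpoints = c(3, 10), levels = c(0, 0.5, 1),
                   direction = "higher_better")
  )
}

#' Score a raw-measure deficit table into Frailty Index values
#'
#' Convenience scorer for one-row-per-participant raw measures: condition,
#' ADL, IADL, Nagi and Rosow-Breslau counts are expanded into their binary
#' items; threshold and graded items are mapped with [map_threshold_items()],
#' [map_graded_performance()] and [map_mini_cog()]; [compute_fi()] then
#' normalizes with the adjusted denominator.
#'
#' @param df data.frame with columns `id`, `conditions_n` (0-21), `adl_n`
#'   (0-6), `iadl_n` (0-8), `nagi_n` (0-4), `rosow_n` (0-3),
#'   `weight_loss_kg`, `bmi`, `smm_kg`, `grip_kg`, `mini_cog` (0-5),
#'   `gait_speed_ms`, `chair_stand_s`, `balance_s`, `sex`.
#' @param gradings Grading specifications, see [fi_default_gradings()].
#' @param ... Passed to [map_threshold_items()].
#' @return data.frame with `id`, `fi`, `n_present`, `n_missing`.
#' @export
score_deficit_table <- function(df, gradings = fi_default_gradings(), ...) {
  counts <- function(x, m) {
    if (any(!is.na(x) & (x < 0 | x > m | x != floor(x))))
      fl_validation_error(sprintf("count outside 0..%d", m))
    t(vapply(x, function(k) {
      if (is.na(k)) rep(NA_real_, m) else c(rep(1, k), rep(0, m - k))
    }, numeric(m)))
  }
  thr <- map_threshold_items(df, ...)
  g <- function(nm, x) map_graded_performance(
    x, gradings[[nm]]$cutpoints, gradings[[nm]]$levels, gradings[[nm]]$direction)
  mat <- cbind(
    counts(df$conditions_n, 21), counts(df$adl_n, 6), counts(df$iadl_n, 8),
    counts(df$nagi_n, 4), counts(df$rosow_n, 3),
    thr$weight_loss, thr$low_bmi, thr$low_smm,
    map_mini_cog(df$mini_cog),
    g("slow_gait", df$gait_speed_ms), g("chair_stand", df$chair_stand_s),
    thr$low_grip, g("balance", df$balance_s))
  res <- apply(mat, 1, function(v) unlist(compute_fi(v)[c("fi", "n_present",
                                                          "n_missing")]))
  data.frame(id = df$id, t(res))
}
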