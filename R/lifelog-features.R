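# Per-participant lifelog predictors: step aggregation, chair-stand
# repetition counting, and self-report means.

#' Daily mean step count
#'
#' Sums steps within each local calendar day and averages over days that have
#' at least one record (a recorded day with zero steps counts as zero).
#'
#' @param records data.frame with columns `t` (UTC epoch seconds) and `steps`.
#' @param tz_offset Local-time offset from UTC, seconds (default +09:00).
#' @return Mean steps/day, or NA if there are no records.
#' @export
daily_mean_steps <- function(records, tz_offset = 9 * 3600) {
  if (!nrow(records)) return(NA_real_)
  if (any(records$steps < 0)) fl_validation_error("steps must be >= 0")
  day <- floor((records$t + tz_offset) / 86400)
  mean(tapply(records$steps, day, sum))
}

#' Hourly mean step count
#'
#' Sums steps within each local clock hour and averages over active hours
#' (hours with at least one step). An hour in which the pedometer recorded
#' only zeros is not active.
#'
#' @inheritParams daily_mean_steps
#' @return Mean steps per active hour, or NA if no hour is active.
#' @export
hourly_mean_steps <- function(records, tz_offset = 9 * 3600) {
  if (!nrow(records)) return(NA_real_)
  if (any(records$steps < 0)) fl_validation_error("steps must be >= 0")
  hour <- floor((records$t + tz_offset) / 3600)
  totals <- tapply(records$steps, hour, sum)
  active <- totals[totals > 0]
  if (!length(active)) return(NA_real_)
  mean(active)
}

# Mean number of active hours per recorded day; with daily_mean_steps and
# hourly_mean_steps it satisfies hourly * active_hours_per_day = daily.
active_hours_per_day <- function(records, tz_offset = 9 * 3600) {
  if (!nrow(records)) return(NA_real_)
  hour <- floor((records$t + tz_offset) / 3600)
  totals <- tapply(records$steps, hour, sum)
  day <- floor((records$t + tz_offset) / 86400)
  sum(totals > 0) / length(unique(day))
}

# Local maxima (strict rise, fall allowing plateaus collapses to first index).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# Topographic prominence of peak i: height above the higher of the two lowest
# saddles separating it from higher ground (or from the signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p - 1L)]
    right <- x[seq(p + 1L, length(x))]
    higher_left <- which(left > x[p])
    higher_right <- which(right > x[p])
    base_left <- min(if (length(higher_left)) left[(max(higher_left)):(p - 1L)]
                     else left)
    base_right <- min(if (length(higher_right))
      right[seq_len(min(higher_right))] else right)
    x[p] - max(base_left, base_right)
  }, 0)
}

#' Count chair-stand repetitions from a 30 s accelerometer trace
#'
#' De-means the vertical acceleration, smooths it with a 0.5 s trailing
#' moving average, and counts peaks with at least `min_prominence` m/s^2 of
#' topographic prominence separated by at least `min_separation` seconds
#' (taller peaks win ties; the separation is enforced with 10% slack so that
#' repetition rates at exactly the separation limit are not undercounted
#' when noise jitters the peak positions).
#'
#' @param trace An `fl_accel_trace` (list with `t`, `az`, `rate`) or any list
#'   with those elements; duration must lie in \[25, 35\] s.
#' @param smooth_s Trailing smoothing span, seconds.
#' @param min_prominence Minimum peak prominence, m/s^2.
#' @param min_separation Minimum peak separation, seconds.
#' @return Integer repetition count.
#' @export
count_sts_reps <- function(trace, smooth_s = 0.5, min_prominence = 0.5,
                           min_separation = 1.0) {
  if (is.null(trace)) return(NA_integer_)
  dur <- length(trace$az) / trace$rate
  if (dur < 25 || dur > 35)
    fl_input_error(sprintf("trace duration %.1f s outside [25, 35] s", dur))
  x <- trailing_mean(trace$az - mean(trace$az),
                     max(1L, round(smooth_s * trace$rate)))
  peaks <- local_maxima(x)
  if (!length(peaks)) return(0L)
  prom <- peak_prominence(x, peaks)
  peaks <- peaks[prom >= min_prominence]
  if (!length(peaks)) return(0L)
  # greedy tallest-first selection under the separation constraint; 10%
  # slack so that cycles at exactly the minimum separation survive the
  # noise-induced jitter of their peak positions
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  kept <- numeric(0)
  min_gap <- 0.9 * min_separation * trace$rate
  for (p in ord) if (!length(kept) || all(abs(kept - p) >= min_gap))
    kept <- c(kept, p)
  length(kept)
}

#' Mean rating of perceived exertion
#'
#' Mean of daily RPE reports on the 15-point scale (1-15); non-integer or
#' out-of-range values are a validation error.
#'
#' @param reports Numeric vector of daily RPE values (NAs = unanswered days).
#' @return Mean RPE, or NA if no day was reported.
#' @export
aggregate_rpe <- function(reports) {
  v <- reports[!is.na(reports)]
  if (!length(v)) return(NA_real_)
  if (any(v != floor(v) | v < 1 | v > 15))
    fl_validation_error("RPE must be an integer in 1..15")
  mean(v)
}

#' Mean subjective health rating
#'
#' Mean of daily subjective-health reports on the 4-point scale coded
#' 1 = very good ... 4 = very bad, so larger means worse self-rated health.
#'
#' @param reports Numeric vector of daily ratings (NAs = unanswered days).
#' @return Mean rating, or NA if no day was reported.
#' @export
aggregate_subjective_health <- function(reports) {
  v <- reports[!is.na(reports)]
  if (!length(v)) return(NA_real_)
  if (any(v != floor(v) | v < 1 | v > 4))
    fl_validation_error("subjective health must be an integer in 1..4")
  mean(v)
}
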