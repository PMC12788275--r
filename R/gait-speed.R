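# GPS usual gait speed: label filter -> temporal clustering -> haversine
# speeds -> physiological band -> duration/radius QC -> environment mask ->
# moving-average smoothing -> pooled mean.

#' Default thresholds of the gait-speed pipeline
#'
#' Minimum cluster size 100 points, maximum intra-cluster gap 300 s, speed
#' band \[0.3, 2.0\] m/s (inclusive), minimum cluster duration 600 s, minimum
#' radius 100 m, 50-point trailing moving average, and a 50% point-overlap
#' rule for the environment mask. All boundaries are inclusive: a gap of
#' exactly 300 s joins, speeds of exactly 0.3 or 2.0 m/s are retained, and
#' clusters of exactly 100 points, 600 s or 100 m survive.
#'
#' @return Named list of thresholds.
#' @export
gait_params <- function() {
  list(min_points = 100L, max_gap_s = 300, band_lo = 0.3, band_hi = 2.0,
       min_duration_s = 600, min_radius_m = 100, smooth_window = 50L,
       mask_overlap = 0.5)
}

#' Retain only points labeled Walking
#'
#' Keeps the subsequence of GPS points whose activity label is exactly
#' `WALKING`, preserving order. Other on-foot labels (`ON_FOOT`) do not pass.
#'
#' @param log data.frame with columns `t`, `lat`, `lon`, `activity`.
#' @return The filtered data.frame.
#' @export
extract_walking_points <- function(log) {
  log[!is.na(log$activity) & log$activity == "WALKING", , drop = FALSE]
}

#' Group walking points into candidate clusters
#'
#' Splits a time-sorted point sequence at gaps greater than `max_gap_s`
#' seconds (a gap of exactly `max_gap_s` joins) and discards runs with fewer
#' than `min_points` points.
#'
#' @param points Time-sorted data.frame of GPS points.
#' @param max_gap_s Maximum inter-point gap within a cluster, seconds.
#' @param min_points Minimum points per cluster.
#' @return List of data.frames, one per surviving cluster.
#' @export
build_clusters <- function(points, max_gap_s = gait_params()$max_gap_s,
                           min_points = gait_params()$min_points) {
  n <- nrow(points)
  if (n == 0L) return(list())
  dt <- diff(points$t)
  if (any(dt < 0)) fl_input_error("points must be time-sorted")
  grp <- cumsum(c(0, dt > max_gap_s))
  runs <- split(points, grp)
  names(runs) <- NULL
  runs[vapply(runs, nrow, 0L) >= min_points]
}

#' Haversine instantaneous speeds within a cluster
#'
#' Computes the great-circle distance (haversine, Earth radius 6,371,000 m)
#' between consecutive points divided by the time gap, giving n-1 speeds for
#' n points. Consecutive points with a zero time gap are degenerate: the pair
#' is dropped and recorded in the `dropped_pairs` attribute rather than
#' failing the cluster.
#'
#' @param cluster data.frame of GPS points (>= 2 rows).
#' @return Numeric vector of speeds (m/s) with attribute `dropped_pairs`.
#' @export
compute_speeds <- function(cluster) {
  n <- nrow(cluster)
  if (n < 2L) fl_input_error("cluster must contain at least 2 points")
  p <- cbind(cluster$lon, cluster$lat)
  d <- geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                                r = EARTH_RADIUS_M)
  dt <- diff(cluster$t)
  degenerate <- dt == 0
  structure(d[!degenerate] / dt[!degenerate],
            dropped_pairs = sum(degenerate))
}

#' Filter speeds to the physiological walking band
#'
#' Keeps speeds in `[band_lo, band_hi]` m/s, inclusive at both ends.
#' Idempotent.
#'
#' @param speeds Numeric vector, m/s.
#' @param band_lo,band_hi Band limits, m/s.
#' @return The filtered subsequence.
#' @export
apply_speed_band <- function(speeds, band_lo = gait_params()$band_lo,
                             band_hi = gait_params()$band_hi) {
  speeds[speeds >= band_lo & speeds <= band_hi]
}

# Cluster radius: maximum haversine distance from the unweighted coordinate
# centroid.
cluster_radius <- function(cluster) {
  centroid <- c(mean(cluster$lon), mean(cluster$lat))
  max(geosphere::distHaversine(centroid, cbind(cluster$lon, cluster$lat),
                               r = EARTH_RADIUS_M))
}

#' Duration and radius quality control
#'
#' Retains clusters lasting at least `min_duration_s` seconds (time span of
#' the original cluster, not of band-surviving pairs) with radius at least
#' `min_radius_m` metres, the radius being the maximum great-circle distance
#' from the cluster's coordinate centroid. Exclusions are logged with a
#' reason (`"duration"` or `"radius"`).
#'
#' @param clusters List of cluster data.frames.
#' @param min_duration_s,min_radius_m QC thresholds.
#' @return List with `clusters` (the survivors) and `qc_log` (a data.frame
#'   of cluster index, duration, radius, kept flag and reason).
#' @export
qc_clusters <- function(clusters, min_duration_s = gait_params()$min_duration_s,
                        min_radius_m = gait_params()$min_radius_m) {
  if (!length(clusters))
    return(list(clusters = list(),
                qc_log = data.frame(cluster = integer(0), duration = numeric(0),
                                    radius = numeric(0), kept = logical(0),
                                    reason = character(0))))
  dur <- vapply(clusters, function(cl) diff(range(cl$t)), 0)
  rad <- vapply(clusters, cluster_radius, 0)
  kept <- dur >= min_duration_s & rad >= min_radius_m
  reason <- ifelse(kept, "",
                   ifelse(dur < min_duration_s, "duration", "radius"))
  list(clusters = clusters[kept],
       qc_log = data.frame(cluster = seq_along(clusters), duration = dur,
                           radius = rad, kept = kept, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Drop clusters overlapping unsuitable environments
#'
#' Automated stand-in for manual map verification: a cluster is dropped when
#' more than `overlap` (default 50%) of its points fall inside any mask
#' polygon. An empty mask is the identity.
#'
#' @param clusters List of cluster data.frames.
#' @param mask List of polygons, each a two-column matrix of (lon, lat)
#'   vertices in WGS84 degrees, e.g. from [read_geojson_mask()].
#' @param overlap Fraction of in-polygon points above which a cluster is
#'   dropped.
#' @return The surviving clusters.
#' @export
apply_environment_mask <- function(clusters, mask = NULL,
                                   overlap = gait_params()$mask_overlap) {
  if (is.null(mask) || !length(mask)) return(clusters)
  mask <- lapply(mask, function(poly) {
    poly <- as.matrix(poly)
    if (ncol(poly) != 2L || nrow(poly) < 3L || any(!is.finite(poly)))
      fl_error("each mask polygon needs >= 3 finite (lon, lat) vertices",
               "frailtylog_geometry_error")
    poly
  })
  keep <- vapply(clusters, function(cl) {
    pts <- cbind(cl$lon, cl$lat)
    inside <- rep(FALSE, nrow(pts))
    for (poly in mask)
      inside <- inside | mgcv::in.out(poly, pts)
    mean(inside) <= overlap
  }, logical(1))
  clusters[keep]
}

#' Read an exclusion-zone mask from GeoJSON
#'
#' Accepts a FeatureCollection (or bare geometry) of Polygon / MultiPolygon
#' features in WGS84 degrees and returns their outer rings as a list of
#' (lon, lat) matrices. Interior rings (holes) are ignored.
#'
#' @param path Path to a GeoJSON file.
#' @return List of polygon matrices suitable for [apply_environment_mask()].
#' @export
read_geojson_mask <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(gj$type %||% "",
                  FeatureCollection = lapply(gj$features, `[[`, "geometry"),
                  Feature = list(gj$geometry),
                  Polygon = , MultiPolygon = list(gj),
                  fl_error("unsupported GeoJSON type",
                           "frailtylog_geometry_error"))
  ring_to_matrix <- function(ring)
    do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
  polys <- list()
  for (g in geoms) {
    if (g$type == "Polygon") {
      polys <- c(polys, list(ring_to_matrix(g$coordinates[[1]])))
    } else if (g$type == "MultiPolygon") {
      polys <- c(polys, lapply(g$coordinates,
                               function(p) ring_to_matrix(p[[1]])))
    } else {
      fl_error("mask features must be Polygon or MultiPolygon",
               "frailtylog_geometry_error")
    }
  }
  polys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smooth speeds with a trailing moving average
#'
#' Length-preserving trailing (causal) moving average: element i is the mean
#' of the last `min(i, window)` values, so the first elements average partial
#' windows.
#'
#' @param speeds Numeric vector, m/s.
#' @param window Window size in samples (>= 1).
#' @return Smoothed vector of the same length.
#' @export
smooth_speeds <- function(speeds, window = gait_params()$smooth_window) {
  if (window < 1) fl_config_error("window must be >= 1")
  trailing_mean(speeds, window)
}

#' Pool valid clusters into a usual gait speed
#'
#' The usual gait speed is the mean of all smoothed, band-limited speed
#' samples pooled across valid clusters, each sample weighted equally.
#' Absence of valid clusters (or of retained samples) is a value, not an
#' error.
#'
#' @param smoothed_speeds List of numeric vectors, one per valid cluster.
#' @param qc_log Optional QC log to attach.
#' @return List of class `fl_gait_result`: `usual_gait_speed` (or NA),
#'   `n_valid_clusters`, `n_speed_samples`, `qc_log`.
#' @export
usual_gait_speed <- function(smoothed_speeds, qc_log = NULL) {
  pooled <- unlist(smoothed_speeds)
  structure(list(
    usual_gait_speed = if (length(pooled)) mean(pooled) else NA_real_,
    n_valid_clusters = length(smoothed_speeds),
    n_speed_samples = length(pooled),
    qc_log = qc_log
  ), class = "fl_gait_result")
}

#' @export
print.fl_gait_result <- function(x, ...) {
  if (is.na(x$usual_gait_speed)) {
    cat("Usual gait speed: not estimable (no valid walking clusters)\n")
  } else {
    cat(sprintf("Usual gait speed: %.3f m/s (%d clusters, %d speed samples)\n",
                x$usual_gait_speed, x$n_valid_clusters, x$n_speed_samples))
  }
  invisible(x)
}

#' Full GPS-to-gait-speed pipeline
#'
#' Applies, in order: Walking-label filtering, temporal clustering with the
#' minimum-size rule, haversine instantaneous speeds, the physiological
#' speed band, duration/radius QC, the environment mask, moving-average
#' smoothing, and pooling into the usual gait speed. Clusters whose speeds
#' are entirely removed by the band filter remain in the cluster count but
#' contribute no samples.
#'
#' @param log data.frame of labeled GPS points (`t`, `lat`, `lon`,
#'   `activity`); duplicate timestamps are de-duplicated before clustering.
#' @param mask Optional polygon mask, see [apply_environment_mask()].
#' @param params Thresholds, see [gait_params()].
#' @return An `fl_gait_result`, see [usual_gait_speed()].
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 1, seed = 3, days = 2,
#'                      gps_noise_sd = 0)
#' truths <- generate_cohort(cfg)
#' log <- simulate_gps_log(truths[1, ], cfg)
#' gait_speed_pipeline(log)
gait_speed_pipeline <- function(log, mask = NULL, params = gait_params()) {
  walking <- extract_walking_points(log)
  walking <- walking[order(walking$t), , drop = FALSE]
  walking <- walking[!duplicated(walking$t), , drop = FALSE]
  clusters <- build_clusters(walking, params$max_gap_s, params$min_points)
  qc <- qc_clusters(clusters, params$min_duration_s, params$min_radius_m)
  valid <- apply_environment_mask(qc$clusters, mask, params$mask_overlap)
  smoothed <- lapply(valid, function(cl) {
    sp <- apply_speed_band(compute_speeds(cl), params$band_lo, params$band_hi)
    smooth_speeds(sp, params$smooth_window)
  })
  usual_gait_speed(smoothed, qc$qc_log)
}
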