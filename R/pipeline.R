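# End-to-end session processing: keypoint tracks in, calibrated diameter
# series out, with per-stage bookkeeping.

#' Full pipeline configuration
#'
#' Aggregates the stage configurations and the analysis window definitions.
#'
#' @param cleaning a [cleaning_config()].
#' @param fit a [robust_fit_config()].
#' @param reference a [reference_config()].
#' @param baseline_frames length of the pre-stimulation baseline window
#'   (default 900 frames = 30 s at 30 fps).
#' @param stim_frames length of the maximum-tolerable-intensity window
#'   (default 270 frames = 9 s at 30 fps).
#' @param likelihood_filter optional threshold in \[0, 1\]: keypoints with
#'   lower tracking likelihood are treated as missing before any processing.
#'   Off (`NULL`) by default — long sessions with stimulation-induced motion
#'   make fixed thresholds impractical, so quality control is left to the
#'   robust fit and the series gates.
#' @param frame_rate frames per second (default 30).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cleaning = cleaning_config(),
                            fit = robust_fit_config(),
                            reference = reference_config(),
                            baseline_frames = 900, stim_frames = 270,
                            likelihood_filter = NULL, frame_rate = 30) {
  if (!is.null(likelihood_filter) &&
      (likelihood_filter < 0 || likelihood_filter > 1)) {
    pk_config_error("likelihood_filter must lie in [0, 1]")
  }
  if (baseline_frames < 1 || stim_frames < 1) {
    pk_config_error("window lengths must be >= 1 frame")
  }
  structure(
    list(cleaning = cleaning, fit = fit, reference = reference,
         baseline_frames = as.integer(baseline_frames),
         stim_frames = as.integer(stim_frames),
         likelihood_filter = likelihood_filter, frame_rate = frame_rate),
    class = "pipeline_config"
  )
}

#' Process one keypoint session into a calibrated diameter series
#'
#' Runs the full chain: optional likelihood gating, sliding-median smoothing
#' of the pupil keypoints, per-frame two-stage robust ellipse fit (area
#' `A = pi a b`), asymmetric IQR gating of the area series, gap-limited
#' linear interpolation, reference-length extraction and cleaning,
#' normalisation `A_norm = A / L^2`, and conversion to diameter in mm.
#' Per-frame fit failures yield missing values and never abort the session.
#'
#' @param track a [track_table()] with bodyparts `P1`-`P8` (boundary) and
#'   the configured reference endpoints.
#' @param config a [pipeline_config()].
#' @return `data.frame` of class `diameter_series` with columns `frame`,
#'   `time_s`, `area_px2`, `ref_len_px`, `area_norm`, `diameter_mm`,
#'   `n_inliers`, `quality_flag`, and a `"counts"` attribute with per-stage
#'   tallies (frames fitted, invalid fits, area outliers removed, gap frames
#'   filled, frames missing in the final series).
#' @export
process_session <- function(track, config = pipeline_config()) {
  pupil <- paste0("P", 1:8)
  missing_bp <- setdiff(pupil, track$bodyparts)
  if (length(missing_bp)) {
    pk_format_error(paste("track lacks pupil bodyparts:",
                          paste(missing_bp, collapse = ", ")))
  }
  n <- n_frames(track)

  if (!is.null(config$likelihood_filter)) {
    thr <- config$likelihood_filter
    low <- !is.na(track$likelihood) & track$likelihood < thr
    track$x[low] <- NA_real_
    track$y[low] <- NA_real_
  }

  # smooth only the pupil keypoints; the reference gets its own cleaning
  smoothed <- track
  pcols <- match(intersect(paste0("P", 1:9), track$bodyparts), track$bodyparts)
  for (j in pcols) {
    smoothed$x[, j] <- sliding_median(track$x[, j], config$cleaning$smooth_window)
    smoothed$y[, j] <- sliding_median(track$y[, j], config$cleaning$smooth_window)
  }

  pidx <- match(pupil, track$bodyparts)
  area <- rep(NA_real_, n)
  n_inliers <- integer(n)
  for (f in seq_len(n)) {
    pts <- if (config$cleaning$pool_frames) {
      pooled_points_for_frame(smoothed, f - 1L,
                              window = config$cleaning$smooth_window)
    } else {
      cbind(smoothed$x[f, pidx], smoothed$y[f, pidx])
    }
    fit <- robust_fit_ellipse(pts, config$fit)
    area[f] <- fit$area_px2
    n_inliers[f] <- fit$n_points_used
  }
  fit_invalid <- is.na(area)

  gated <- suppressWarnings(remove_area_outliers(
    area, config$cleaning$iqr_low_factor, config$cleaning$iqr_high_factor
  ))
  area_outlier <- !fit_invalid & is.na(gated)
  filled <- interpolate_gaps(gated, config$cleaning$max_gap)
  interpolated <- is.na(gated) & !is.na(filled)

  ref_raw <- reference_length(track, config$reference$endpoint_pair)
  ref_clean <- clean_reference(ref_raw, config$reference, config$cleaning)
  a_norm <- normalize_area(filled, ref_clean, config$reference$min_valid_px)
  diam <- diameter_mm(a_norm, config$reference$ref_mm)

  flag <- rep("ok", n)
  flag[interpolated] <- "interpolated"
  no_diam <- is.na(diam)
  flag[no_diam & area_outlier] <- "area_outlier"
  flag[no_diam & fit_invalid] <- "invalid_fit"
  flag[no_diam & !fit_invalid & !area_outlier & !is.na(filled)] <- "no_reference"
  flag[no_diam & flag == "ok"] <- "missing"

  out <- data.frame(
    frame = track$frame,
    time_s = track$frame / config$frame_rate,
    area_px2 = area,
    ref_len_px = ref_clean,
    area_norm = a_norm,
    diameter_mm = diam,
    n_inliers = n_inliers,
    quality_flag = flag,
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- list(
    n_frames = n,
    frames_fitted = sum(!fit_invalid),
    fit_invalid = sum(fit_invalid),
    area_outliers_removed = sum(area_outlier),
    gap_frames_filled = sum(interpolated),
    frames_missing_final = sum(is.na(diam))
  )
  class(out) <- c("diameter_series", "data.frame")
  out
}

#' Default analysis windows for a processed session
#'
#' Baseline = the first `baseline_frames` frames; stimulation = the last
#' `stim_frames` frames (the recording ends at the maximum tolerable
#' intensity).
#'
#' @param n_frames session length in frames.
#' @param config a [pipeline_config()].
#' @return list with `baseline` and `stim`, each `c(first, last)` (0-based,
#'   inclusive).
#' @export
default_windows <- function(n_frames, config = pipeline_config()) {
  if (n_frames < config$baseline_frames + config$stim_frames) {
    pk_insufficient_data_error(sprintf(
      "session has %d frames; need at least %d for the default windows",
      n_frames, config$baseline_frames + config$stim_frames
    ))
  }
  list(
    baseline = c(0L, config$baseline_frames - 1L),
    stim = c(n_frames - config$stim_frames, n_frames - 1L)
  )
}
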