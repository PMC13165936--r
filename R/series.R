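# Temporal cleaning: sliding-median smoothing of keypoint coordinates,
# multi-frame point pooling, asymmetric IQR gating of the area series, and
# gap-limited linear interpolation.

#' Cleaning configuration for keypoint and area time series
#'
#' @param smooth_window sliding-median window in frames (odd, default 3).
#' @param smooth_step step of the sliding window in frames (default 1; only
#'   1 is supported, kept for config completeness).
#' @param iqr_low_factor lower IQR gate factor for the area series
#'   (default 1.5): values below `Q1 - iqr_low_factor * IQR` become missing.
#' @param iqr_high_factor upper IQR gate factor (default 3.0): values above
#'   `Q3 + iqr_high_factor * IQR` become missing. The asymmetry reflects that
#'   blink-driven artefacts deflate the fitted area far more often than they
#'   inflate it.
#' @param max_gap longest run of missing frames that linear interpolation
#'   will bridge (default 30 frames, about 1 s at 30 fps).
#' @param pool_frames if `TRUE`, the ellipse is fitted to the union of
#'   boundary points over the smoothing window (up to 24 points for a
#'   3-frame window) instead of one frame's 8 points.
#' @return list of class `cleaning_config`.
#' @export
cleaning_config <- function(smooth_window = 3, smooth_step = 1,
                            iqr_low_factor = 1.5, iqr_high_factor = 3.0,
                            max_gap = 30, pool_frames = FALSE) {
  if (smooth_window < 1 || smooth_window %% 2 != 1) {
    pk_config_error("smooth_window must be odd and >= 1")
  }
  if (smooth_step != 1) pk_config_error("only smooth_step = 1 is supported")
  if (iqr_low_factor <= 0 || iqr_high_factor <= 0) {
    pk_config_error("IQR factors must be > 0")
  }
  if (max_gap < 0) pk_config_error("max_gap must be >= 0")
  structure(
    list(smooth_window = as.integer(smooth_window), smooth_step = 1L,
         iqr_low_factor = iqr_low_factor, iqr_high_factor = iqr_high_factor,
         max_gap = as.integer(max_gap), pool_frames = isTRUE(pool_frames)),
    class = "cleaning_config"
  )
}

# centred sliding median of one numeric vector, NA-skipping, window shrinking
# at the series edges; all-NA windows stay NA
sliding_median <- function(v, window) {
  n <- length(v)
  if (n == 0 || window == 1) return(v)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- stats::median(v[lo:hi], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Sliding-median smoothing of keypoint coordinates
#'
#' Applies a centred sliding median (default window 3 frames, step 1) to the
#' x- and y-coordinate series of every keypoint independently, damping
#' single-frame tracking jitter from camera or head movements. Missing values
#' are skipped within each window; a window with no present values stays
#' missing; at the series edges the window shrinks to the available frames.
#'
#' @param track a [track_table()].
#' @param window odd window length in frames.
#' @return A smoothed [track_table()] of identical shape (likelihoods are
#'   passed through unchanged).
#' @export
sliding_median_coords <- function(track, window = 3) {
  if (window %% 2 != 1 || window < 1) pk_config_error("window must be odd and >= 1")
  x <- track$x; y <- track$y
  for (j in seq_len(ncol(x))) {
    x[, j] <- sliding_median(x[, j], window)
    y[, j] <- sliding_median(y[, j], window)
  }
  out <- track
  out$x <- x
  out$y <- y
  out
}

#' Pool pupil-boundary points across consecutive frames
#'
#' Returns the union of all present boundary-keypoint coordinates over a
#' centred window around `frame` — up to `8 * window` points (24 for a
#' 3-frame window) — for use as ellipse-fit input when a richer point set is
#' wanted than one frame's 8 markers.
#'
#' @param track a [track_table()].
#' @param frame 0-based frame index.
#' @param window window length in frames (centred; shrinks at the edges).
#' @param bodyparts which keypoints to pool (default `P1`–`P8`).
#' @return two-column matrix of (x, y); zero rows if nothing is present.
#' @export
pooled_points_for_frame <- function(track, frame, window = 3,
                                    bodyparts = paste0("P", 1:8)) {
  n <- n_frames(track)
  if (frame < 0 || frame >= n) pk_contract_error("frame outside the session")
  half <- (window - 1L) %/% 2L
  rows <- (max(0L, frame - half):min(n - 1L, frame + half)) + 1L
  cols <- match(bodyparts, track$bodyparts)
  cols <- cols[!is.na(cols)]
  xs <- as.vector(track$x[rows, cols, drop = FALSE])
  ys <- as.vector(track$y[rows, cols, drop = FALSE])
  keep <- is.finite(xs) & is.finite(ys)
  cbind(x = xs[keep], y = ys[keep])
}

#' Asymmetric IQR gating of a scalar series
#'
#' Computes Q1, Q3 and the IQR over the present values (linear-interpolation
#' quantiles) and replaces values strictly outside
#' `[Q1 - low_factor * IQR, Q3 + high_factor * IQR]` with `NA`; the bounds
#' themselves are inclusive. With fewer than 4 present values the series is
#' returned unchanged with a warning.
#'
#' @param values numeric vector (e.g. pupil area in px^2), `NA` = missing.
#' @param low_factor,high_factor gate factors (defaults 1.5 and 3.0).
#' @return numeric vector: each element either equals the input or is `NA`.
#' @export
remove_area_outliers <- function(values, low_factor = 1.5, high_factor = 3.0) {
  if (low_factor <= 0 || high_factor <= 0) pk_config_error("factors must be > 0")
  present <- values[!is.na(values)]
  if (length(present) < 4) {
    warning("fewer than 4 present values; outlier gate skipped")
    return(values)
  }
  q <- stats::quantile(present, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - low_factor * iqr
  hi <- q[2] + high_factor * iqr
  out <- values
  out[!is.na(values) & (values < lo | values > hi)] <- NA_real_
  out
}

#' Gap-limited linear interpolation
#'
#' Fills every maximal run of missing values that is no longer than
#' `max_gap` frames *and* flanked on both sides by present values, by linear
#' interpolation between the flanking values. Longer runs, and runs touching
#' either end of the series, are left missing (no extrapolation): sustained
#' blinks or occlusions cannot be reconstructed reliably.
#'
#' @param values numeric vector with `NA` for missing.
#' @param max_gap longest gap (in frames) to bridge (default 30, ~1 s at
#'   30 fps).
#' @return numeric vector of the same length; present values are never
#'   altered.
#' @export
interpolate_gaps <- function(values, max_gap = 30) {
  if (max_gap < 0) pk_config_error("max_gap must be >= 0")
  if (sum(!is.na(values)) < 2 || max_gap == 0) return(values)
  as.numeric(zoo::na.approx(values, maxgap = max_gap, na.rm = FALSE))
}
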