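# Synthetic keypoint sessions with known ground truth: noisy elliptical
# boundary rings, a reference marker with slow uniform scale drift, blink
# gaps, and sporadic gross keypoint outliers. Used to exercise the full
# pipeline without videos or a trained network.

#' Configuration for the synthetic session generator
#'
#' Defaults emulate the acquisition geometry of a webcam pupillometry
#' session: 30 frames/s, an 8 mm reference-endpoint separation, a resting
#' pupil diameter of 5.7 mm, and a camera scale of 20 px/mm.
#'
#' @param n_frames number of frames to generate.
#' @param frame_rate frames per second (default 30).
#' @param px_per_mm camera scale in pixels per millimetre (default 20).
#' @param baseline_diameter_mm resting pupil diameter (default 5.7 mm).
#' @param dilation_events list of events, each a list with `onset_frame`,
#'   `duration_frames` (plateau), `amplitude_mm`, `rise_frames` (linear rise
#'   and fall lengths). Event profiles add to the baseline diameter.
#' @param ellipse_axis_ratio pupil axis ratio `b/a` in (0, 1] (default 0.9;
#'   the off-axis camera makes the imaged pupil mildly elliptical).
#' @param orientation_rad pupil ellipse orientation (default 0.4 rad).
#' @param keypoint_noise_px isotropic Gaussian noise s.d. on every visible
#'   keypoint coordinate (default 0.5 px).
#' @param blink_rate_per_min expected blink count per minute (default 10).
#' @param blink_duration_frames inclusive range of blink lengths in frames
#'   (default `c(6, 12)`, i.e. 200-400 ms at 30 fps).
#' @param outlier_prob per-frame, per-boundary-keypoint probability of a
#'   gross mislocalisation (default 0).
#' @param outlier_shift_px displacement magnitude of an outlier keypoint
#'   (default 30 px, about half the pupil semi-axis at the default scale).
#' @param scale_drift_amplitude relative amplitude of a slow sinusoidal
#'   uniform scale change (one cycle per session; default 0) emulating head
#'   or camera motion along the optical axis.
#' @param ref_mm physical separation of the S2-S4 reference endpoints
#'   (default 8 mm).
#' @param seed integer seed; sessions are bitwise reproducible given the
#'   seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_frames = 900, frame_rate = 30, px_per_mm = 20,
                         baseline_diameter_mm = 5.7, dilation_events = list(),
                         ellipse_axis_ratio = 0.9, orientation_rad = 0.4,
                         keypoint_noise_px = 0.5,
                         blink_rate_per_min = 10,
                         blink_duration_frames = c(6, 12),
                         outlier_prob = 0, outlier_shift_px = 30,
                         scale_drift_amplitude = 0, ref_mm = 8, seed = 1L) {
  if (n_frames < 1) pk_config_error("n_frames must be >= 1")
  if (px_per_mm <= 0 || baseline_diameter_mm <= 0 || frame_rate <= 0) {
    pk_config_error("px_per_mm, baseline_diameter_mm, frame_rate must be > 0")
  }
  if (ellipse_axis_ratio <= 0 || ellipse_axis_ratio > 1) {
    pk_config_error("ellipse_axis_ratio must lie in (0, 1]")
  }
  if (outlier_prob < 0 || outlier_prob >= 1) {
    pk_config_error("outlier_prob must lie in [0, 1)")
  }
  if (keypoint_noise_px < 0 || outlier_shift_px < 0 ||
      blink_rate_per_min < 0 || scale_drift_amplitude < 0) {
    pk_config_error("noise, shift, blink rate and drift amplitude must be >= 0")
  }
  if (length(blink_duration_frames) != 2 ||
      blink_duration_frames[1] > blink_duration_frames[2] ||
      blink_duration_frames[1] < 1) {
    pk_config_error("blink_duration_frames must be c(min, max) with min >= 1")
  }
  structure(
    list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
         px_per_mm = px_per_mm, baseline_diameter_mm = baseline_diameter_mm,
         dilation_events = dilation_events,
         ellipse_axis_ratio = ellipse_axis_ratio,
         orientation_rad = orientation_rad,
         keypoint_noise_px = keypoint_noise_px,
         blink_rate_per_min = blink_rate_per_min,
         blink_duration_frames = as.integer(blink_duration_frames),
         outlier_prob = outlier_prob, outlier_shift_px = outlier_shift_px,
         scale_drift_amplitude = scale_drift_amplitude,
         ref_mm = ref_mm, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# trapezoidal event profile added to the baseline diameter
event_profile <- function(frames, ev) {
  rise <- max(1L, as.integer(ev$rise_frames))
  local <- frames - ev$onset_frame
  amp <- ev$amplitude_mm
  up <- local >= 0 & local < rise
  flat <- local >= rise & local < rise + ev$duration_frames
  down <- local >= rise + ev$duration_frames &
    local < 2 * rise + ev$duration_frames
  out <- numeric(length(frames))
  out[up] <- amp * (local[up] + 1) / rise
  out[flat] <- amp
  out[down] <- amp * (1 - (local[down] - rise - ev$duration_frames + 1) / rise)
  pmax(out, 0)
}

#' Generate a synthetic keypoint session with ground truth
#'
#' Per frame, the true pupil diameter is the baseline plus the sum of active
#' dilation-event profiles. The true ellipse preserves the equivalent-area
#' circle (`a * b = (D/2 * s)^2` in px, with axis ratio `b/a` free), so any
#' axis ratio reproduces the same diameter through the area-based pipeline.
#' Eight boundary keypoints (P1-P8) sit at 45 degree parameter intervals on
#' the true boundary plus isotropic Gaussian noise; P9 is the noisy centre;
#' the reference endpoints S1-S4 are placed so that `|S2 - S4|` equals
#' `ref_mm` at the instantaneous scale. A slow sinusoidal drift multiplies
#' *all* coordinates uniformly (camera-distance change). Blinks blank all
#' pupil keypoints; outliers displace single boundary keypoints by
#' `outlier_shift_px` in a random direction. Likelihood is 1.0, reduced
#' below 0.2 for blanked or displaced points.
#'
#' Random draws occur in a fixed documented order (blink count, onsets,
#' durations; coordinate noise; outlier indicators; outlier directions), so
#' identical configurations yield bitwise-identical sessions. The caller's
#' RNG state is preserved.
#'
#' @param cfg a [synth_config()].
#' @return list with `track` (a [track_table()]) and `truth` (class
#'   `session_ground_truth`: per-frame true ellipse parameters, diameter,
#'   reference length, blink and outlier masks).
#' @export
generate_session <- function(cfg = synth_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  n <- cfg$n_frames
  frames <- seq_len(n) - 1L

  # true diameter trace
  diam <- rep(cfg$baseline_diameter_mm, n)
  for (ev in cfg$dilation_events) diam <- diam + event_profile(frames, ev)

  # uniform scale: one slow sinusoidal cycle per session
  drift <- cfg$scale_drift_amplitude * sin(2 * pi * frames / n)
  s <- cfg$px_per_mm * (1 + drift)

  r <- cfg$ellipse_axis_ratio
  a_px <- (diam / 2) * s / sqrt(r)
  b_px <- (diam / 2) * s * sqrt(r)
  centre_mm <- c(16, 12)
  xc <- centre_mm[1] * s
  yc <- centre_mm[2] * s

  # reference marker: two short parallel segments 10 mm below the pupil;
  # S2-S4 is the calibrated pair
  ref_layout <- list(
    S1 = c(-4, 11), S2 = c(-4, 10), S3 = c(4, 11), S4 = c(4, 10)
  )

  # draw 1: blinks
  minutes <- n / cfg$frame_rate / 60
  n_blinks <- stats::rpois(1, cfg$blink_rate_per_min * minutes)
  blink_mask <- rep(FALSE, n)
  if (n_blinks > 0) {
    onsets <- sample.int(n, n_blinks, replace = TRUE) - 1L
    dur_lo <- cfg$blink_duration_frames[1]
    dur_hi <- cfg$blink_duration_frames[2]
    durs <- dur_lo + sample.int(dur_hi - dur_lo + 1L, n_blinks, replace = TRUE) - 1L
    for (k in seq_len(n_blinks)) {
      span <- onsets[k]:min(n - 1L, onsets[k] + durs[k] - 1L)
      blink_mask[span + 1L] <- TRUE
    }
  }

  # draw 2: coordinate noise for P1..P9 (x block then y block)
  noise_x <- matrix(stats::rnorm(n * 9, sd = cfg$keypoint_noise_px), n, 9)
  noise_y <- matrix(stats::rnorm(n * 9, sd = cfg$keypoint_noise_px), n, 9)

  # draw 3 + 4: outlier indicators and directions for P1..P8
  out_mask <- matrix(stats::runif(n * 8) < cfg$outlier_prob, n, 8)
  out_mask[blink_mask, ] <- FALSE
  out_angle <- matrix(stats::runif(n * 8, 0, 2 * pi), n, 8)

  bodyparts <- c(paste0("P", 1:9), paste0("S", 1:4))
  X <- Y <- L <- matrix(NA_real_, n, 13, dimnames = list(NULL, bodyparts))

  sp <- sin(cfg$orientation_rad); cp <- cos(cfg$orientation_rad)
  angles <- (0:7) * pi / 4
  for (k in 1:8) {
    u <- a_px * cos(angles[k])
    v <- b_px * sin(angles[k])
    X[, k] <- xc + cp * u - sp * v + noise_x[, k]
    Y[, k] <- yc + sp * u + cp * v + noise_y[, k]
  }
  X[, 9] <- xc + noise_x[, 9]
  Y[, 9] <- yc + noise_y[, 9]
  L[, 1:9] <- 1.0

  # displace outlier keypoints
  for (k in 1:8) {
    hit <- out_mask[, k]
    X[hit, k] <- X[hit, k] + cfg$outlier_shift_px * cos(out_angle[hit, k])
    Y[hit, k] <- Y[hit, k] + cfg$outlier_shift_px * sin(out_angle[hit, k])
    L[hit, k] <- 0.1
  }

  # blank pupil keypoints during blinks
  X[blink_mask, 1:9] <- NA_real_
  Y[blink_mask, 1:9] <- NA_real_
  L[blink_mask, 1:9] <- 0.05

  # reference endpoints (noise-free: the printed marker is high contrast and
  # tracked far more stably than the pupil boundary)
  for (sname in names(ref_layout)) {
    off <- ref_layout[[sname]]
    X[, sname] <- (centre_mm[1] + off[1]) * s
    Y[, sname] <- (centre_mm[2] + off[2]) * s
    L[, sname] <- 1.0
  }
  ref_len_px <- cfg$ref_mm * s  # |S2 - S4| by construction

  track <- track_table(X, Y, L, bodyparts, frame_rate = cfg$frame_rate)
  truth <- structure(
    list(
      frame = frames,
      diameter_mm = diam,
      ref_len_px = ref_len_px,
      xc = xc, yc = yc, a_px = a_px, b_px = b_px,
      phi = rep(cfg$orientation_rad, n),
      blink = blink_mask,
      outlier_mask = out_mask,
      n_outliers = rowSums(out_mask),
      config = cfg
    ),
    class = "session_ground_truth"
  )
  list(track = track, truth = truth)
}

#' Ground-truth pupillary response of a synthetic session
#'
#' Window means of the true diameter trace; the reference value for
#' parameter-recovery tests.
#'
#' @param truth a `session_ground_truth`.
#' @param baseline_window,stim_window inclusive 0-based frame ranges
#'   `c(first, last)`.
#' @return response in mm (stimulation mean minus baseline mean).
#' @export
ground_truth_response <- function(truth, baseline_window, stim_window) {
  n <- length(truth$diameter_mm)
  grab <- function(win, label) {
    if (length(win) != 2 || win[1] > win[2] || win[1] < 0 || win[2] >= n) {
      pk_contract_error(sprintf("%s window outside the session", label))
    }
    mean(truth$diameter_mm[(win[1]:win[2]) + 1])
  }
  grab(stim_window, "stimulation") - grab(baseline_window, "baseline")
}

#' Write a ground-truth CSV for a synthetic session
#'
#' @param truth a `session_ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  df <- data.frame(
    frame = truth$frame,
    true_diameter_mm = truth$diameter_mm,
    true_ref_px = truth$ref_len_px,
    blink = as.integer(truth$blink),
    outlier_count = truth$n_outliers
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
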