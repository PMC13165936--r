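# Reference-marker scale handling: per-frame reference length, its cleaning,
# area normalisation A/L^2, and conversion to absolute diameter in mm.

#' Reference-marker configuration
#'
#' The skin-mounted reference marker provides a per-frame pixel length of
#' known physical size, which cancels uniform camera-scale changes (head or
#' camera translation along the optical axis) via the normalisation
#' `A_norm = A / L^2`.
#'
#' @param endpoint_pair names of the two endpoint keypoints whose separation
#'   is calibrated (default `c("S2", "S4")`, the most stable pair).
#' @param min_px,max_px manual plausibility gates on the pixel length; if
#'   `NULL` (default) they are set per session to +/-50% of the session
#'   median reference length.
#' @param min_valid_px numeric guard: frames whose reference length does not
#'   exceed this are treated as missing during normalisation
#'   (default 1e-6 px, a division-by-near-zero guard).
#' @param ref_mm physical separation of the endpoint pair in millimetres
#'   (default 8).
#' @return list of class `reference_config`.
#' @export
reference_config <- function(endpoint_pair = c("S2", "S4"),
                             min_px = NULL, max_px = NULL,
                             min_valid_px = 1e-6, ref_mm = 8) {
  if (length(endpoint_pair) != 2) pk_config_error("endpoint_pair must name two bodyparts")
  if (!is.null(min_px) && !is.null(max_px) && min_px >= max_px) {
    pk_config_error("min_px must be < max_px")
  }
  if (ref_mm <= 0) pk_config_error("ref_mm must be > 0")
  if (min_valid_px < 0) pk_config_error("min_valid_px must be >= 0")
  structure(
    list(endpoint_pair = as.character(endpoint_pair),
         min_px = min_px, max_px = max_px,
         min_valid_px = min_valid_px, ref_mm = ref_mm),
    class = "reference_config"
  )
}

#' Per-frame reference length in pixels
#'
#' Euclidean distance between the two reference endpoints,
#' `L = sqrt((Xi - Xj)^2 + (Yi - Yj)^2)`, computed frame by frame; missing
#' whenever either endpoint is missing in that frame.
#'
#' @param track a [track_table()].
#' @param pair character vector of two bodypart names.
#' @return numeric vector, one length (px) per frame.
#' @export
reference_length <- function(track, pair = c("S2", "S4")) {
  cols <- match(pair, track$bodyparts)
  if (anyNA(cols)) {
    pk_config_error(sprintf("unknown bodypart(s): %s",
                            paste(pair[is.na(cols)], collapse = ", ")))
  }
  dx <- track$x[, cols[1]] - track$x[, cols[2]]
  dy <- track$y[, cols[1]] - track$y[, cols[2]]
  sqrt(dx^2 + dy^2)
}

#' Clean a reference-length series
#'
#' Three stages, in order: (1) manual plausibility gate — values outside
#' `[min_px, max_px]` become missing (defaults: +/-50% of the session
#' median); (2) symmetric IQR outlier removal (1.5 x IQR both sides,
#' distinct from the asymmetric area gate); (3) gap-limited linear
#' interpolation, reusing [interpolate_gaps()].
#'
#' @param values numeric vector of per-frame reference lengths (px).
#' @param cfg a [reference_config()].
#' @param cleaning a [cleaning_config()] (supplies `max_gap`).
#' @return cleaned numeric vector, same length.
#' @export
clean_reference <- function(values, cfg = reference_config(),
                            cleaning = cleaning_config()) {
  out <- values
  med <- stats::median(out, na.rm = TRUE)
  min_px <- if (is.null(cfg$min_px)) 0.5 * med else cfg$min_px
  max_px <- if (is.null(cfg$max_px)) 1.5 * med else cfg$max_px
  out[!is.na(out) & (out < min_px | out > max_px)] <- NA_real_
  out <- remove_area_outliers(out, low_factor = 1.5, high_factor = 1.5)
  interpolate_gaps(out, max_gap = cleaning$max_gap)
}

#' Normalise pupil area by the squared reference length
#'
#' `A_norm = A / L^2`, computed only for frames in which both the area and
#' the reference length are present and `L` exceeds `min_valid_px`; all
#' other frames are missing. The result is dimensionless and invariant to
#' uniform rescaling of the image.
#'
#' @param area numeric vector, pupil area per frame (px^2).
#' @param ref_len numeric vector, reference length per frame (px); same
#'   length as `area`.
#' @param min_valid_px near-zero guard on `L` (default 1e-6 px).
#' @return numeric vector of dimensionless normalised areas.
#' @export
normalize_area <- function(area, ref_len, min_valid_px = 1e-6) {
  if (length(area) != length(ref_len)) {
    pk_contract_error("area and ref_len must have equal length")
  }
  ok <- !is.na(area) & !is.na(ref_len) & ref_len > min_valid_px
  out <- rep(NA_real_, length(area))
  out[ok] <- area[ok] / ref_len[ok]^2
  out
}

#' Convert normalised area to absolute pupil diameter in millimetres
#'
#' `D = ref_mm * 2 * sqrt(A_norm / pi)`: the diameter of the circle whose
#' area equals the pupil area, expressed in mm through the known physical
#' separation of the reference endpoints. Applied per frame or to
#' window-averaged normalised areas.
#'
#' @param a_norm dimensionless normalised area (vectorised); `NA` passes
#'   through.
#' @param ref_mm physical reference separation in mm (default 8).
#' @return numeric vector of diameters in mm.
#' @export
diameter_mm <- function(a_norm, ref_mm = 8) {
  if (any(a_norm < 0, na.rm = TRUE)) {
    pk_contract_error("a_norm must be non-negative")
  }
  ref_mm * 2 * sqrt(a_norm / pi)
}
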