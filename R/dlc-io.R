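# Reading/writing the DeepLabCut single-animal CSV dialect and the
# pipeline's flat diameter table.

#' Construct a keypoint track table
#'
#' A `track_table` holds one recording session of markerless keypoint tracks:
#' per-frame x/y pixel coordinates and a likelihood score in \[0, 1\] for each
#' named bodypart. Coordinates use the image convention (origin top-left,
#' y increasing downward); frames are indexed from 0 and must be contiguous.
#' Missing coordinates (occlusions, blinks) are encoded as `NA`; the
#' likelihood of a missing record is treated as 0 downstream.
#'
#' @param x,y numeric matrices, frames x bodyparts, pixel coordinates.
#' @param likelihood numeric matrix, frames x bodyparts, values in \[0, 1\]
#'   or `NA`.
#' @param bodyparts character vector of bodypart names (column order).
#' @param frame_rate frames per second; the CSV carries no timing, so this is
#'   configuration (default 30).
#' @return An object of class `track_table` with fields `x`, `y`,
#'   `likelihood`, `bodyparts`, `frame` (0-based) and `frame_rate`.
#' @export
track_table <- function(x, y, likelihood, bodyparts, frame_rate = 30) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(likelihood))) {
    pk_contract_error("x, y and likelihood must have identical dimensions")
  }
  if (ncol(x) != length(bodyparts)) {
    pk_contract_error("number of columns must equal number of bodyparts")
  }
  bad_lik <- likelihood[!is.na(likelihood)]
  if (length(bad_lik) && (any(bad_lik < 0) || any(bad_lik > 1))) {
    pk_contract_error("likelihood values must lie in [0, 1]")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    pk_config_error("frame_rate must be a positive scalar")
  }
  dimnames(x) <- dimnames(y) <- dimnames(likelihood) <- list(NULL, bodyparts)
  structure(
    list(
      x = x, y = y, likelihood = likelihood,
      bodyparts = as.character(bodyparts),
      frame = seq_len(nrow(x)) - 1L,
      frame_rate = frame_rate
    ),
    class = "track_table"
  )
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf(
    "<track_table> %d frames, %d bodyparts (%s), %g fps\n",
    n_frames(x), length(x$bodyparts),
    paste(utils::head(x$bodyparts, 6), collapse = ", "),
    x$frame_rate
  ))
  invisible(x)
}

#' Number of frames in a track table
#' @param track a `track_table`.
#' @return integer frame count.
#' @export
n_frames <- function(track) nrow(track$x)

#' Read a DeepLabCut-style keypoint CSV
#'
#' Parses the single-animal CSV dialect: three header rows labelled
#' `scorer`, `bodyparts` and `coords`, then one numeric row per frame. Each
#' bodypart must declare an `x`, `y`, `likelihood` column triplet (in that
#' order). Empty cells become `NA`. Frame indices may start anywhere but must
#' be strictly increasing and contiguous; they are re-based to 0.
#'
#' @param path path to the CSV file.
#' @param frame_rate frames per second to attach (default 30).
#' @return A [track_table()].
#' @export
read_dlc_csv <- function(path, frame_rate = 30) {
  if (!file.exists(path)) pk_format_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 3) {
    pk_format_error("expected 3 header rows (scorer/bodyparts/coords)")
  }
  labels <- tolower(trimws(raw[1:3, 1]))
  if (!identical(labels, c("scorer", "bodyparts", "coords"))) {
    pk_format_error(sprintf(
      "expected header rows labelled scorer/bodyparts/coords, found: %s",
      paste(raw[1:3, 1], collapse = "/")
    ))
  }
  bp_row <- as.character(raw[2, -1])
  coord_row <- tolower(trimws(as.character(raw[3, -1])))
  bodyparts <- unique(bp_row)
  for (bp in bodyparts) {
    idx <- which(bp_row == bp)
    if (length(idx) != 3 || !identical(coord_row[idx], c("x", "y", "likelihood"))) {
      pk_format_error(sprintf(
        "bodypart '%s' must declare an x, y, likelihood column triplet", bp
      ))
    }
  }
  data <- raw[-(1:3), , drop = FALSE]
  if (nrow(data) == 0) pk_format_error("no data rows after the header")

  parse_num <- function(col, name) {
    col <- trimws(col)
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "" & is.na(out))
    if (length(bad)) {
      pk_format_error(sprintf(
        "non-numeric value '%s' at data row %d, column '%s'",
        col[bad[1]], bad[1], name
      ))
    }
    out
  }

  frame_idx <- parse_num(data[[1]], "frame")
  if (anyNA(frame_idx)) pk_format_error("missing frame index in data rows")
  if (anyDuplicated(frame_idx)) {
    pk_format_error(sprintf("duplicate frame index %g", frame_idx[anyDuplicated(frame_idx)]))
  }
  if (any(diff(frame_idx) <= 0)) {
    pk_format_error("frame indices must be strictly increasing")
  }
  if (any(diff(frame_idx) != 1)) {
    pk_format_error("frame indices must be contiguous")
  }

  nf <- nrow(data); nb <- length(bodyparts)
  x <- y <- lik <- matrix(NA_real_, nf, nb)
  for (j in seq_along(bodyparts)) {
    idx <- which(bp_row == bodyparts[j]) + 1L  # +1: skip frame column
    x[, j] <- parse_num(data[[idx[1]]], paste0(bodyparts[j], ".x"))
    y[, j] <- parse_num(data[[idx[2]]], paste0(bodyparts[j], ".y"))
    lik[, j] <- parse_num(data[[idx[3]]], paste0(bodyparts[j], ".likelihood"))
  }
  track_table(x, y, lik, bodyparts, frame_rate = frame_rate)
}

fmt_full <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else sprintf("%.17g", z)
  }, character(1))
  out
}

#' Write a track table as a DeepLabCut-style CSV
#'
#' Inverse of [read_dlc_csv()]: coordinates are serialised at full double
#' precision so that a write/read roundtrip is exact; `NA` becomes an empty
#' cell.
#'
#' @param track a [track_table()].
#' @param path output path.
#' @param scorer value for the scorer header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path, scorer = "pupilkit") {
  nb <- length(track$bodyparts)
  header1 <- c("scorer", rep(scorer, 3 * nb))
  header2 <- c("bodyparts", rep(track$bodyparts, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), nb))
  body <- matrix("", n_frames(track), 1 + 3 * nb)
  body[, 1] <- as.character(track$frame)
  for (j in seq_len(nb)) {
    body[, 3 * j - 1] <- fmt_full(track$x[, j])
    body[, 3 * j]     <- fmt_full(track$y[, j])
    body[, 3 * j + 1] <- fmt_full(track$likelihood[, j])
  }
  lines <- c(
    paste(header1, collapse = ","),
    paste(header2, collapse = ","),
    paste(header3, collapse = ","),
    apply(body, 1, paste, collapse = ",")
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

diameter_columns <- c(
  "frame", "time_s", "area_px2", "ref_len_px", "area_norm",
  "diameter_mm", "n_inliers", "quality_flag"
)

#' Write a diameter series table as a flat CSV
#'
#' Columns: `frame`, `time_s`, `area_px2`, `ref_len_px`, `area_norm`,
#' `diameter_mm`, `n_inliers`, `quality_flag`. Missing values are serialised
#' as empty cells.
#'
#' @param series a `data.frame` as produced by [process_session()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diameter_csv <- function(series, path) {
  if (!is.data.frame(series) || nrow(series) == 0) {
    pk_contract_error("series must be a non-empty data.frame")
  }
  missing_cols <- setdiff(diameter_columns, names(series))
  if (length(missing_cols)) {
    pk_contract_error(paste("series lacks columns:",
                            paste(missing_cols, collapse = ", ")))
  }
  out <- series[, diameter_columns]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a diameter series CSV written by [write_diameter_csv()]
#'
#' @param path path to the CSV.
#' @return `data.frame` with the diameter-series columns; empty cells read
#'   back as `NA`.
#' @export
read_diameter_csv <- function(path) {
  if (!file.exists(path)) pk_format_error(sprintf("file not found: %s", path))
  out <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(diameter_columns, names(out))
  if (length(missing_cols)) {
    pk_format_error(paste("diameter CSV lacks columns:",
                          paste(missing_cols, collapse = ", ")))
  }
  out
}
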