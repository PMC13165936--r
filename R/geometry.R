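# Ellipse geometry: algebraic conic fitting, conic <-> geometric parameter
# conversion, orthogonal point-to-ellipse distance, and the two-stage robust
# fit used to turn pupil-boundary keypoints into an area estimate.

conic_names <- c("a", "b", "c", "d", "e", "f")

#' Fit a conic section to scattered points by algebraic least squares
#'
#' Solves `a x^2 + b xy + c y^2 + d x + e y + f = 0` in the least-squares
#' sense: the returned unit-norm coefficient vector minimises the algebraic
#' residual `||M v||` over `||v|| = 1`, where the rows of the design matrix
#' `M` are `(x^2, xy, y^2, x, y, 1)`, via singular value decomposition.
#'
#' For numerical conditioning, and so that the fit commutes exactly with
#' similarity transforms of the input (translation, rotation, uniform
#' scaling), the points are internally centred on their centroid and scaled
#' to unit RMS radius before the decomposition, with the cross term weighted
#' so the constraint is rotation invariant; the conic is then mapped back to
#' the original coordinates. The sign is fixed so that `a >= 0`.
#'
#' @param points two-column matrix (x, y) of at least 5 distinct,
#'   non-collinear points, in pixels.
#' @return Named numeric vector `(a, b, c, d, e, f)` with unit Euclidean
#'   norm, of class `conic`.
#' @export
fit_conic_lsq <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2) pk_contract_error("points must be a two-column matrix")
  keep <- is.finite(points[, 1]) & is.finite(points[, 2])
  points <- points[keep, , drop = FALSE]
  if (nrow(unique(points)) < 5) {
    pk_degenerate_error("need at least 5 distinct points to fit a conic")
  }
  ctr <- colMeans(points)
  xc <- points[, 1] - ctr[1]
  yc <- points[, 2] - ctr[2]
  s <- sqrt(mean(xc^2 + yc^2))
  if (s == 0) pk_degenerate_error("points are coincident")
  xn <- xc / s
  yn <- yc / s

  # sqrt(2) weight on the xy column makes the unit-norm constraint invariant
  # under rotations of the (centred) data
  w <- sqrt(2)
  M <- cbind(xn^2, w * xn * yn, yn^2, xn, yn, 1)
  sv <- svd(M, nu = 0, nv = 6)
  if (sv$d[5] <= 1e-10 * sv$d[1]) {
    pk_degenerate_error("degenerate point configuration (collinear or coincident points)")
  }
  u <- sv$v[, 6]
  vn <- c(u[1], w * u[2], u[3], u[4], u[5], u[6])  # conic in normalised frame

  # map back: x' = (x - tx)/s, y' = (y - ty)/s
  tx <- ctr[1]; ty <- ctr[2]
  a <- vn[1] / s^2
  b <- vn[2] / s^2
  c_ <- vn[3] / s^2
  d <- (-2 * vn[1] * tx - vn[2] * ty) / s^2 + vn[4] / s
  e <- (-vn[2] * tx - 2 * vn[3] * ty) / s^2 + vn[5] / s
  f <- (vn[1] * tx^2 + vn[2] * tx * ty + vn[3] * ty^2) / s^2 -
    (vn[4] * tx + vn[5] * ty) / s + vn[6]

  v <- c(a, b, c_, d, e, f)
  v <- v / sqrt(sum(v^2))
  sgn <- if (v[1] != 0) sign(v[1]) else if (v[3] != 0) sign(v[3]) else 1
  v <- v * sgn
  names(v) <- conic_names
  class(v) <- "conic"
  v
}

#' Construct an ellipse geometry object
#'
#' @param xc,yc centre, pixels.
#' @param a_semi,b_semi semi-major and semi-minor axes, pixels
#'   (`a_semi >= b_semi > 0`).
#' @param phi orientation of the major axis, radians, reduced to `[0, pi)`.
#' @return list of class `ellipse_geometry`.
#' @export
ellipse_geometry <- function(xc, yc, a_semi, b_semi, phi = 0) {
  if (!is.finite(a_semi) || !is.finite(b_semi) || b_semi <= 0 || a_semi < b_semi) {
    pk_contract_error("require a_semi >= b_semi > 0")
  }
  phi <- phi %% pi
  structure(list(xc = xc, yc = yc, a_semi = a_semi, b_semi = b_semi, phi = phi),
            class = "ellipse_geometry")
}

#' @export
print.ellipse_geometry <- function(x, ...) {
  cat(sprintf(
    "<ellipse> centre (%.3f, %.3f), semi-axes (%.3f, %.3f), phi = %.4f rad\n",
    x$xc, x$yc, x$a_semi, x$b_semi, x$phi
  ))
  invisible(x)
}

#' Convert conic coefficients to geometric ellipse parameters
#'
#' Closed-form conversion of `(a, b, c, d, e, f)` to centre, semi-axes and
#' orientation. The conic must describe a real ellipse (`b^2 - 4ac < 0` and
#' positive axis lengths); anything else (parabola, hyperbola, imaginary or
#' degenerate conic) raises a classed non-ellipse error, which callers use to
#' mark the frame invalid rather than abort.
#'
#' @param conic coefficient vector as returned by [fit_conic_lsq()].
#' @return An [ellipse_geometry()].
#' @export
conic_to_ellipse <- function(conic) {
  v <- unclass(conic)
  if (length(v) != 6 || !all(is.finite(v))) {
    pk_contract_error("conic must be 6 finite coefficients")
  }
  A <- v[[1]]; B <- v[[2]]; C <- v[[3]]; D <- v[[4]]; E <- v[[5]]; F_ <- v[[6]]
  disc <- B^2 - 4 * A * C
  if (disc >= 0) {
    pk_stop("pupilkit_nonellipse_error", "conic is not an ellipse (b^2 - 4ac >= 0)")
  }
  xc <- (2 * C * D - B * E) / disc
  yc <- (2 * A * E - B * D) / disc
  core <- 2 * (A * E^2 + C * D^2 - B * D * E + disc * F_)
  root <- sqrt((A - C)^2 + B^2)
  num_major <- core * (A + C + root)
  num_minor <- core * (A + C - root)
  if (num_major < 0 || num_minor < 0) {
    pk_stop("pupilkit_nonellipse_error", "conic is an imaginary or degenerate ellipse")
  }
  a_semi <- -sqrt(num_major) / disc
  b_semi <- -sqrt(num_minor) / disc
  if (!is.finite(a_semi) || !is.finite(b_semi) || b_semi <= 0) {
    pk_stop("pupilkit_nonellipse_error", "conic is a degenerate ellipse")
  }
  phi <- if (abs(B) <= .Machine$double.eps * (abs(A) + abs(C))) {
    if (A <= C) 0 else pi / 2
  } else {
    atan2(C - A - root, B)
  }
  ellipse_geometry(xc, yc, a_semi, b_semi, phi)
}

#' Convert geometric ellipse parameters to unit-norm conic coefficients
#'
#' Exact inverse of [conic_to_ellipse()] (up to the unit-norm, `a >= 0` sign
#' convention).
#'
#' @param ellipse an [ellipse_geometry()].
#' @return Named numeric vector of class `conic`.
#' @export
ellipse_to_conic <- function(ellipse) {
  a <- ellipse$a_semi; b <- ellipse$b_semi
  xc <- ellipse$xc; yc <- ellipse$yc; phi <- ellipse$phi
  sp <- sin(phi); cp <- cos(phi)
  A <- a^2 * sp^2 + b^2 * cp^2
  B <- 2 * (b^2 - a^2) * sp * cp
  C <- a^2 * cp^2 + b^2 * sp^2
  D <- -2 * A * xc - B * yc
  E <- -B * xc - 2 * C * yc
  F_ <- A * xc^2 + B * xc * yc + C * yc^2 - a^2 * b^2
  v <- c(A, B, C, D, E, F_)
  v <- v / sqrt(sum(v^2))
  if (v[1] < 0) v <- -v
  names(v) <- conic_names
  class(v) <- "conic"
  v
}

#' Points on an ellipse boundary
#'
#' @param ellipse an [ellipse_geometry()].
#' @param angles boundary parameter values (radians); the point at parameter
#'   `t` is `centre + R(phi) (a cos t, b sin t)`.
#' @return two-column matrix of (x, y) coordinates.
#' @export
ellipse_points <- function(ellipse, angles) {
  sp <- sin(ellipse$phi); cp <- cos(ellipse$phi)
  u <- ellipse$a_semi * cos(angles)
  v <- ellipse$b_semi * sin(angles)
  cbind(x = ellipse$xc + cp * u - sp * v,
        y = ellipse$yc + sp * u + cp * v)
}

#' Orthogonal distance from points to an ellipse boundary
#'
#' Computes the true Euclidean (perpendicular) distance from each point to
#' the ellipse boundary. Points are mapped into the ellipse frame and folded
#' into the first quadrant; the boundary parameter of the nearest point is
#' located on a coarse grid over `[0, pi/2]` and polished by safeguarded
#' Newton iteration on the stationarity condition (step tolerance 1e-12,
#' at most 50 iterations). The `algebraic` method instead returns the
#' absolute algebraic residual of the unit-norm conic at each point; it is
#' cheaper but biased by eccentricity and position.
#'
#' @param points two-column matrix of (x, y), or a length-2 vector.
#' @param ellipse an [ellipse_geometry()].
#' @param method `"geometric"` (default) or `"algebraic"`.
#' @return Numeric vector of distances, `>= 0`; `NA` for non-finite points.
#' @export
point_ellipse_distance <- function(points, ellipse, method = c("geometric", "algebraic")) {
  method <- match.arg(method)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  if (method == "algebraic") {
    v <- ellipse_to_conic(ellipse)
    x <- points[, 1]; y <- points[, 2]
    return(abs(v[1] * x^2 + v[2] * x * y + v[3] * y^2 + v[4] * x + v[5] * y + v[6]))
  }
  a <- ellipse$a_semi; b <- ellipse$b_semi
  sp <- sin(ellipse$phi); cp <- cos(ellipse$phi)
  dx <- points[, 1] - ellipse$xc
  dy <- points[, 2] - ellipse$yc
  # rotate into the ellipse frame and fold into the first quadrant
  qa <- abs(cp * dx + sp * dy)
  qb <- abs(-sp * dx + cp * dy)
  out <- rep(NA_real_, nrow(points))
  ok <- is.finite(qa) & is.finite(qb)
  if (!any(ok)) return(out)
  qa_ <- qa[ok]; qb_ <- qb[ok]

  if (abs(a - b) < 1e-14 * a) {           # circle: radial distance
    out[ok] <- abs(sqrt(qa_^2 + qb_^2) - a)
    return(out)
  }

  gfun <- function(theta) (a * cos(theta) - qa_)^2 + (b * sin(theta) - qb_)^2
  # coarse grid argmin over the quadrant
  grid <- seq(0, pi / 2, length.out = 17)
  gbest <- gfun(0)
  theta <- numeric(length(qa_))
  for (t in grid[-1]) {
    gt <- gfun(t)
    better <- gt < gbest
    theta[better] <- t
    gbest[better] <- gt[better]
  }
  # safeguarded Newton on g'(theta) = 0
  for (iter in seq_len(50)) {
    st <- sin(theta); ct <- cos(theta)
    g1 <- 2 * ((b^2 - a^2) * st * ct + a * qa_ * st - b * qb_ * ct)
    g2 <- 2 * ((b^2 - a^2) * (ct^2 - st^2) + a * qa_ * ct + b * qb_ * st)
    step <- ifelse(g2 > 0, g1 / g2, sign(g1) * 0.1)
    theta_new <- pmin(pi / 2, pmax(0, theta - step))
    gnew <- gfun(theta_new)
    worse <- gnew > gbest
    # halve rejected steps once; keep old value if still worse
    if (any(worse)) {
      theta_half <- (theta[worse] + theta_new[worse]) / 2
      ghalf <- (a * cos(theta_half) - qa_[worse])^2 + (b * sin(theta_half) - qb_[worse])^2
      use_half <- ghalf <= gbest[worse]
      theta_new[worse][use_half] <- theta_half[use_half]
      gnew[worse][use_half] <- ghalf[use_half]
      theta_new[worse][!use_half] <- theta[worse][!use_half]
      gnew[worse][!use_half] <- gbest[worse][!use_half]
    }
    moved <- abs(theta_new - theta)
    theta <- theta_new
    gbest <- gnew
    if (max(moved) < 1e-12) break
  }
  out[ok] <- sqrt(pmax(0, gbest))
  out
}

#' Configuration for the two-stage robust ellipse fit
#'
#' @param k_iqr multiplier for the `median + k * IQR` distance threshold.
#'   The conventional Tukey factor 1.5 is the default.
#' @param alpha absolute-threshold factor: points farther than
#'   `alpha * a0` from the initial fit (with `a0` its semi-major axis) are
#'   excluded. Default 0.1.
#' @param min_points minimum keypoints required for a valid fit (>= 5).
#' @param distance distance definition used in the outlier step:
#'   `"geometric"` (orthogonal, default) or `"algebraic"`.
#' @return list of class `robust_fit_config`.
#' @export
robust_fit_config <- function(k_iqr = 1.5, alpha = 0.1, min_points = 5,
                              distance = c("geometric", "algebraic")) {
  distance <- match.arg(distance)
  if (!is.numeric(k_iqr) || k_iqr <= 0) pk_config_error("k_iqr must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    pk_config_error("alpha must lie in (0, 1)")
  }
  if (min_points < 5) pk_config_error("min_points must be >= 5")
  structure(list(k_iqr = k_iqr, alpha = alpha, min_points = as.integer(min_points),
                 distance = distance),
            class = "robust_fit_config")
}

invalid_fit <- function(n) {
  structure(list(ellipse = NULL, inlier_flags = rep(FALSE, n),
                 area_px2 = NA_real_, n_points_used = 0L, valid = FALSE),
            class = "robust_fit")
}

#' Two-stage robust ellipse fit
#'
#' Fits an initial conic to all valid (finite) points, measures each point's
#' distance to the initial ellipse, excludes points with distance strictly
#' greater than `median + k_iqr * IQR` of the distances *or* greater than
#' `alpha * a0` (with `a0` the initial semi-major axis), and refits on the
#' surviving inliers. If fewer than `min_points` points survive at any stage,
#' or either fit is not a real ellipse, the result is marked invalid with a
#' missing area — per-frame failures are values, never errors, so one bad
#' frame cannot abort a session.
#'
#' @param points two-column matrix of keypoint coordinates; non-finite rows
#'   are treated as missing markers.
#' @param config a [robust_fit_config()].
#' @return list of class `robust_fit` with fields `ellipse`
#'   ([ellipse_geometry()] or `NULL`), `inlier_flags` (per input row),
#'   `area_px2` (`pi * a * b`, `NA` if invalid), `n_points_used`, `valid`.
#' @export
robust_fit_ellipse <- function(points, config = robust_fit_config()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  n <- nrow(points)
  finite <- if (n) is.finite(points[, 1]) & is.finite(points[, 2]) else logical(0)
  if (sum(finite) < config$min_points) return(invalid_fit(n))
  pts <- points[finite, , drop = FALSE]

  initial <- tryCatch(
    conic_to_ellipse(fit_conic_lsq(pts)),
    pupilkit_error = function(e) NULL
  )
  if (is.null(initial)) return(invalid_fit(n))

  d <- point_ellipse_distance(pts, initial, method = config$distance)
  thr <- stats::median(d) + config$k_iqr * stats::IQR(d, type = 7)
  keep <- d <= thr & d <= config$alpha * initial$a_semi
  if (sum(keep) < config$min_points) return(invalid_fit(n))

  refined <- tryCatch(
    conic_to_ellipse(fit_conic_lsq(pts[keep, , drop = FALSE])),
    pupilkit_error = function(e) NULL
  )
  if (is.null(refined)) return(invalid_fit(n))

  flags <- rep(FALSE, n)
  flags[which(finite)[keep]] <- TRUE
  structure(
    list(ellipse = refined, inlier_flags = flags,
         area_px2 = pi * refined$a_semi * refined$b_semi,
         n_points_used = sum(keep), valid = TRUE),
    class = "robust_fit"
  )
}

#' @export
print.robust_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<robust_fit> valid, %d inliers, area %.3f px^2\n",
                x$n_points_used, x$area_px2))
  } else {
    cat("<robust_fit> invalid (too few points or degenerate fit)\n")
  }
  invisible(x)
}
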