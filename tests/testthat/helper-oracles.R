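# Independent oracles used across the suite. These deliberately avoid the
# implementation's code paths.

# brute-force two-sided exact Wilcoxon signed-rank p-value by enumerating
# all 2^n sign assignments over the actual mid-ranks (n <= ~15)
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_obs <- min(w_plus, sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wp <- as.vector(signs %*% r)
  total <- sum(r)
  wmin <- pmin(wp, total - wp)
  # P(W+ <= w_obs) * 2, capped; equivalent to 2 * min-tail by symmetry
  min(1, 2 * mean(wp <= w_obs + 1e-9))
}

# distance from a point to an ellipse by dense parameter sweep + local
# refinement (independent of the Newton projection)
oracle_ellipse_distance <- function(p, ellipse, grid_n = 4000) {
  f <- function(th) {
    q <- ellipse_points(ellipse, th)
    sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2)
  }
  grid <- seq(0, 2 * pi, length.out = grid_n + 1)
  gv <- vapply(grid, f, numeric(1))
  k <- which.min(gv)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(grid_n + 1, k + 1)]
  stats::optimize(f, c(lo, hi), tol = 1e-13)$objective
}

# independently coded algebraic conic fit: same normalised least-squares
# problem, solved by eigen-decomposition of the normal matrix rather than
# SVD of the design matrix
oracle_conic_fit <- function(pts) {
  ctr <- colMeans(pts)
  xc <- pts[, 1] - ctr[1]
  yc <- pts[, 2] - ctr[2]
  s <- sqrt(mean(xc^2 + yc^2))
  xn <- xc / s; yn <- yc / s
  w <- sqrt(2)
  M <- cbind(xn^2, w * xn * yn, yn^2, xn, yn, 1)
  ev <- eigen(crossprod(M), symmetric = TRUE)
  u <- ev$vectors[, 6]
  vn <- c(u[1], w * u[2], u[3], u[4], u[5], u[6])
  tx <- ctr[1]; ty <- ctr[2]
  v <- c(vn[1] / s^2, vn[2] / s^2, vn[3] / s^2,
         (-2 * vn[1] * tx - vn[2] * ty) / s^2 + vn[4] / s,
         (-vn[2] * tx - 2 * vn[3] * ty) / s^2 + vn[5] / s,
         (vn[1] * tx^2 + vn[2] * tx * ty + vn[3] * ty^2) / s^2 -
           (vn[4] * tx + vn[5] * ty) / s + vn[6])
  v <- v / sqrt(sum(v^2))
  if (v[1] < 0) v <- -v
  v
}

# conic coefficients of an ellipse derived independently from the implicit
# quadratic form (p - c)' R diag(1/a^2, 1/b^2) R' (p - c) = 1
oracle_ellipse_conic <- function(xc, yc, a, b, phi) {
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  Q <- R %*% diag(c(1 / a^2, 1 / b^2)) %*% t(R)
  A <- Q[1, 1]; B <- 2 * Q[1, 2]; C <- Q[2, 2]
  D <- -2 * A * xc - B * yc
  E <- -B * xc - 2 * C * yc
  F_ <- A * xc^2 + B * xc * yc + C * yc^2 - 1
  v <- c(A, B, C, D, E, F_)
  v <- v / sqrt(sum(v^2))
  if (v[1] < 0) v <- -v
  v
}

# build a small DeepLabCut-dialect CSV fixture on disk; values is a list
# bodypart -> matrix(n_frames x 3) of x, y, likelihood
write_dlc_fixture <- function(path, values, frames = NULL,
                              drop_likelihood_for = NULL) {
  bps <- names(values)
  n <- nrow(values[[1]])
  if (is.null(frames)) frames <- seq_len(n) - 1L
  h1 <- c("scorer"); h2 <- c("bodyparts"); h3 <- c("coords")
  for (bp in bps) {
    cols <- if (bp %in% drop_likelihood_for) c("x", "y") else c("x", "y", "likelihood")
    h1 <- c(h1, rep("model", length(cols)))
    h2 <- c(h2, rep(bp, length(cols)))
    h3 <- c(h3, cols)
  }
  rows <- character(n)
  for (i in seq_len(n)) {
    cells <- as.character(frames[i])
    for (bp in bps) {
      v <- values[[bp]][i, ]
      if (bp %in% drop_likelihood_for) v <- v[1:2]
      cells <- c(cells, ifelse(is.na(v), "", format(v, digits = 17)))
    }
    rows[i] <- paste(cells, collapse = ",")
  }
  writeLines(c(paste(h1, collapse = ","), paste(h2, collapse = ","),
               paste(h3, collapse = ","), rows), path)
  path
}

# standard 13-bodypart fixture values: all keypoints at simple positions
make_fixture_values <- function(n_frames = 2) {
  bps <- c(paste0("P", 1:9), paste0("S", 1:4))
  vals <- lapply(seq_along(bps), function(j) {
    cbind(x = seq_len(n_frames) + j, y = seq_len(n_frames) * 2 + j,
          likelihood = rep(1.0, n_frames))
  })
  names(vals) <- bps
  vals
}
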