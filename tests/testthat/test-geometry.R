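circle_points <- function(n = 8, r = 1, xc = 0, yc = 0) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(xc + r * cos(th), yc + r * sin(th))
}

test_that("conic fit recovers canonical circles and axis-aligned ellipses", {
  co <- fit_conic_lsq(circle_points(8))
  # proportional to (1, 0, 1, 0, 0, -1)
  expect_equal(unclass(co) / co[1], c(a = 1, b = 0, c = 1, d = 0, e = 0, f = -1),
               tolerance = 1e-12)

  pts <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1), c(sqrt(2), sqrt(2) / 2))
  co2 <- fit_conic_lsq(pts)
  expect_equal(unclass(co2) / co2[1], c(a = 1, b = 0, c = 4, d = 0, e = 0, f = -4),
               tolerance = 1e-9)
})

test_that("conic fit on noisy ellipse points matches the independent oracle", {
  set.seed(101)
  e <- ellipse_geometry(5, 4, 3, 2, pi / 6)
  for (rep in 1:20) {
    pts <- ellipse_points(e, (0:7) * pi / 4)
    pts <- pts + matrix(rnorm(16, sd = 0.01), 8, 2)
    co <- fit_conic_lsq(pts)
    oc <- oracle_conic_fit(pts)
    expect_equal(unname(unclass(co)), unname(oc), tolerance = 1e-10)
    # algebraic residual small: points near the fitted conic
    resid <- abs(co[1] * pts[, 1]^2 + co[2] * pts[, 1] * pts[, 2] +
                   co[3] * pts[, 2]^2 + co[4] * pts[, 1] + co[5] * pts[, 2] + co[6])
    expect_lt(max(resid), 10 * 0.01)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_conic_lsq(circle_points(4)), class = "pupilkit_degenerate_error")
  # 5 distinct but collinear points
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(fit_conic_lsq(line), class = "pupilkit_degenerate_error")
  # duplicates reduce the distinct count below 5
  dup <- rbind(circle_points(4), circle_points(4))
  expect_error(fit_conic_lsq(dup), class = "pupilkit_degenerate_error")
})

test_that("conic to ellipse conversion is exact on canonical and general conics", {
  v <- c(1, 0, 1, 0, 0, -1) / sqrt(3)
  class(v) <- "conic"
  e <- conic_to_ellipse(v)
  expect_equal(c(e$xc, e$yc, e$a_semi, e$b_semi), c(0, 0, 1, 1), tolerance = 1e-12)

  # conic derived independently from the quadratic form of a rotated ellipse
  oc <- oracle_ellipse_conic(5, 4, 3, 2, pi / 6)
  class(oc) <- "conic"
  e2 <- conic_to_ellipse(oc)
  expect_equal(c(e2$xc, e2$yc, e2$a_semi, e2$b_semi, e2$phi),
               c(5, 4, 3, 2, pi / 6), tolerance = 1e-9)

  # hyperbola
  h <- c(1, 0, -1, 0, 0, -1) / sqrt(3)
  class(h) <- "conic"
  expect_error(conic_to_ellipse(h), class = "pupilkit_nonellipse_error")
})

test_that("ellipse to conic and back is the identity", {
  set.seed(5)
  for (rep in 1:25) {
    e <- ellipse_geometry(runif(1, -100, 100), runif(1, -100, 100),
                          a <- runif(1, 1, 50), runif(1, 0.2, 1) * a,
                          runif(1, 0, pi))
    e2 <- conic_to_ellipse(ellipse_to_conic(e))
    expect_equal(unlist(e2[c("xc", "yc", "a_semi", "b_semi")]),
                 unlist(e[c("xc", "yc", "a_semi", "b_semi")]),
                 tolerance = 1e-9)
    if (e$a_semi / e$b_semi > 1 + 1e-6) {
      expect_equal(e2$phi, e$phi, tolerance = 1e-8)
    }
  }
})

test_that("point-to-ellipse distance handles canonical geometry", {
  circle <- ellipse_geometry(0, 0, 1, 1, 0)
  expect_equal(point_ellipse_distance(c(2, 0), circle), 1.0, tolerance = 1e-12)
  # centre of a 2:1 ellipse: nearest boundary point is on the minor axis
  e <- ellipse_geometry(0, 0, 2, 1, 0)
  expect_equal(point_ellipse_distance(c(0, 0), e), 1.0, tolerance = 1e-12)
  # boundary point has zero distance
  expect_equal(point_ellipse_distance(ellipse_points(e, 0.73), e), 0,
               tolerance = 1e-10)
  # interior point on the major axis, inside the evolute: nearest point is
  # off-axis (a classical trap for naive projections)
  d <- point_ellipse_distance(c(0.5, 0), e)
  expect_equal(d, oracle_ellipse_distance(c(0.5, 0), e), tolerance = 1e-9)
  expect_lt(d, 1.5)  # strictly closer than the on-axis vertex
})

test_that("point-to-ellipse distance matches dense-sweep minimisation", {
  expect_equal(point_ellipse_distance(c(3, 1), ellipse_geometry(0, 0, 2, 1, 0)),
               oracle_ellipse_distance(c(3, 1), ellipse_geometry(0, 0, 2, 1, 0)),
               tolerance = 1e-6)
  set.seed(77)
  for (rep in 1:50) {
    a <- runif(1, 0.5, 30)
    e <- ellipse_geometry(runif(1, -20, 20), runif(1, -20, 20),
                          a, runif(1, 0.1, 1) * a, runif(1, 0, pi))
    p <- runif(2, -60, 60)
    expect_equal(point_ellipse_distance(p, e), oracle_ellipse_distance(p, e),
                 tolerance = 1e-6)
  }
})

test_that("fit is equivariant under similarity transforms", {
  set.seed(9)
  e <- ellipse_geometry(5, 4, 3, 2, pi / 7)
  pts <- ellipse_points(e, sort(runif(8, 0, 2 * pi)))
  base <- conic_to_ellipse(fit_conic_lsq(pts))
  # rotation + translation
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(-12, 7)
  moved <- sweep(pts %*% t(R), 2, shift, "+")
  em <- conic_to_ellipse(fit_conic_lsq(moved))
  cen <- R %*% c(base$xc, base$yc) + shift
  expect_equal(c(em$xc, em$yc), as.vector(cen), tolerance = 1e-9)
  expect_equal(em$a_semi, base$a_semi, tolerance = 1e-9)
  expect_equal(em$b_semi, base$b_semi, tolerance = 1e-9)
  expect_equal(em$phi %% pi, (base$phi + th) %% pi, tolerance = 1e-8)
  # uniform scaling: semi-axes scale by s, area by s^2
  s <- 3.7
  es <- conic_to_ellipse(fit_conic_lsq(pts * s))
  expect_equal(es$a_semi, s * base$a_semi, tolerance = 1e-9)
  expect_equal(es$b_semi, s * base$b_semi, tolerance = 1e-9)
})

test_that("robust fit on clean points keeps everything and reproduces A = pi a b", {
  e <- ellipse_geometry(0, 0, 3, 2, 0)
  pts <- ellipse_points(e, (0:7) * pi / 4)
  rf <- robust_fit_ellipse(pts)
  expect_true(rf$valid)
  expect_true(all(rf$inlier_flags))
  expect_equal(rf$n_points_used, 8L)
  expect_equal(rf$area_px2, 6 * pi, tolerance = 1e-9)
  # refined fit equals initial fit (no exclusions on exact points)
  expect_equal(rf$ellipse$a_semi, 3, tolerance = 1e-9)
  expect_equal(rf$ellipse$b_semi, 2, tolerance = 1e-9)
})

test_that("robust fit returns an invalid value (not an error) below 5 points", {
  pts <- ellipse_points(ellipse_geometry(0, 0, 3, 2, 0), (0:3) * pi / 2)
  rf <- robust_fit_ellipse(pts)
  expect_false(rf$valid)
  expect_true(is.na(rf$area_px2))
  expect_equal(rf$n_points_used, 0L)
  # empty input
  rf0 <- robust_fit_ellipse(matrix(numeric(0), 0, 2))
  expect_false(rf0$valid)
  # non-finite rows are dropped as missing markers
  pts8 <- ellipse_points(ellipse_geometry(0, 0, 3, 2, 0), (0:7) * pi / 4)
  pts8[1:4, 1] <- NA
  expect_false(robust_fit_ellipse(pts8)$valid)
})

test_that("outlier exclusion rule is monotone in k_iqr and alpha", {
  set.seed(13)
  e <- ellipse_geometry(10, -3, 4, 3, 1)
  for (rep in 1:20) {
    pts <- ellipse_points(e, (0:7) * pi / 4) + matrix(rnorm(16, sd = 0.15), 8, 2)
    kept <- sapply(c(0.5, 1.5, 3), function(k) {
      sum(robust_fit_ellipse(pts, robust_fit_config(k_iqr = k))$inlier_flags)
    })
    expect_true(all(diff(kept) >= 0))
    kept_a <- sapply(c(0.05, 0.1, 0.5), function(al) {
      sum(robust_fit_ellipse(pts, robust_fit_config(alpha = al))$inlier_flags)
    })
    expect_true(all(diff(kept_a) >= 0))
  }
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(robust_fit_config(k_iqr = 0), class = "pupilkit_config_error")
  expect_error(robust_fit_config(alpha = 1.5), class = "pupilkit_config_error")
  expect_error(robust_fit_config(min_points = 4), class = "pupilkit_config_error")
})
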