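# Non-parametric statistics used by the validation and stimulation-response
# analyses: median [Q1; Q3] summaries with median-exclusive-halves quartiles,
# an exact Wilcoxon signed-rank test (ties via mid-ranks), non-parametric
# Bland-Altman agreement, Spearman correlation, a Shapiro-Wilk normality
# gate, and the pupillary-response statistic.

# median-exclusive-halves quartiles: for odd n the overall median is excluded
# from both halves; each quartile is the median of its half
quartiles_exclusive <- function(sorted) {
  n <- length(sorted)
  half <- n %/% 2
  lower <- sorted[seq_len(half)]
  upper <- sorted[(n - half + 1):n]
  c(q1 = stats::median(lower), q3 = stats::median(upper))
}

#' Median with interquartile range
#'
#' Summarises a sample as `median [Q1; Q3]`. Quartiles use the
#' median-exclusive-halves rule by default: the sample is split at the
#' median (for odd n the median itself is excluded from both halves) and
#' each quartile is the median of its half. An interpolation-quantile
#' alternative (R's type 7) is available for sensitivity checks.
#'
#' @param values numeric vector, `NA` dropped; at least 3 present values.
#' @param quartile_rule `"exclusive_halves"` (default) or `"interpolation"`.
#' @return list of class `median_iqr` with `median`, `q1`, `q3`, `n`.
#' @export
summarize_median_iqr <- function(values,
                                 quartile_rule = c("exclusive_halves", "interpolation")) {
  quartile_rule <- match.arg(quartile_rule)
  v <- sort(values[!is.na(values)])
  if (length(v) < 3) pk_contract_error("need at least 3 present values")
  med <- stats::median(v)
  q <- if (quartile_rule == "exclusive_halves") {
    quartiles_exclusive(v)
  } else {
    stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  }
  structure(list(median = med, q1 = unname(q[1]), q3 = unname(q[2]),
                 n = length(v)),
            class = "median_iqr")
}

#' @export
print.median_iqr <- function(x, ...) {
  cat(sprintf("%g [%g; %g] (n = %d)\n", x$median, x$q1, x$q3, x$n))
  invisible(x)
}

# exact null distribution of 2*W+ for signed ranks r (mid-ranks allowed):
# counts over achievable doubled rank sums, by subset-sum convolution
wplus_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), f[seq_len(total + 1 - r)])
    f <- f + shifted
  }
  f  # f[k+1] = number of sign assignments with 2*W+ == k
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `d = x - y`; zero differences are dropped (Wilcoxon's
#' original rule); `|d|` is ranked with mid-ranks for ties; the statistic is
#' `W = min(W+, W-)`. For `n_effective <= 25` the two-sided p-value is exact,
#' computed from the full null distribution of the signed-rank sum over all
#' `2^n` sign assignments with the actual mid-ranks (so ties are handled
#' exactly); beyond that a normal approximation with tie correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest `n_effective` for which the exact distribution is
#'   enumerated (default 25).
#' @return list of class `wilcoxon_result`: `w_statistic`, `w_plus`,
#'   `n_effective`, `p_two_sided`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) pk_contract_error("x and y must have equal length")
  if (length(x) < 1) pk_contract_error("need at least one pair")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) pk_degenerate_error("all differences are zero; test undefined")
  r <- rank(abs(d), ties.method = "average")
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    f <- wplus_counts(ranks2)
    k <- as.integer(round(2 * w))
    p <- min(1, 2 * sum(f[seq_len(k + 1)]) / 2^n)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(w_statistic = w, w_plus = w_plus, n_effective = n,
                 p_two_sided = p, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.4g (%s)\n",
              x$w_statistic, x$n_effective, x$p_two_sided, x$method))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Mid-rank Spearman correlation. The p-value is exact (full permutation
#' null distribution) for `n <= 10` with untied data, and otherwise uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) pk_contract_error("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) pk_contract_error("need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    pk_degenerate_error("zero variance in ranks; correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 10 && !has_ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    )
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Royston approximation, used as a reported
#' normality gate before the non-parametric analyses; its outcome never
#' switches methods silently.
#'
#' @param values numeric vector, 3 to 5000 present values, non-constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 3 || length(v) > 5000) {
    pk_contract_error("Shapiro-Wilk requires between 3 and 5000 present values")
  }
  if (stats::sd(v) == 0) pk_contract_error("values are constant; test undefined")
  res <- stats::shapiro.test(v)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Non-parametric Bland-Altman agreement analysis
#'
#' For paired measurements of the same quantity by two methods, summarises
#' the differences `m1 - m2` non-parametrically: bias as the median
#' difference with \[Q1; Q3\] (median-exclusive-halves quartiles), limits of
#' agreement as the 2.5th and 97.5th percentiles of the differences
#' (interpolation quantiles), plus the Spearman correlation between the two
#' methods. If the correlation is undefined (e.g. identical methods) it is
#' reported missing with a warning.
#'
#' @param m1,m2 paired numeric vectors, at least 4 complete pairs.
#' @return list of class `agreement_report`: `bias_median`, `bias_q1`,
#'   `bias_q3`, `loa_low`, `loa_high`, `spearman_rho`, `spearman_p`,
#'   `n_pairs`.
#' @export
bland_altman_nonparametric <- function(m1, m2) {
  if (length(m1) != length(m2)) pk_contract_error("m1 and m2 must have equal length")
  ok <- !is.na(m1) & !is.na(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  if (length(m1) < 4) pk_insufficient_data_error("need at least 4 complete pairs")
  d <- m1 - m2
  s <- summarize_median_iqr(d)
  loa <- stats::quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
  sp <- tryCatch(spearman_rho(m1, m2), pupilkit_error = function(e) {
    warning("Spearman correlation undefined: ", conditionMessage(e))
    list(rho = NA_real_, p = NA_real_)
  })
  structure(
    list(bias_median = s$median, bias_q1 = s$q1, bias_q3 = s$q3,
         loa_low = loa[1], loa_high = loa[2],
         spearman_rho = sp$rho, spearman_p = sp$p, n_pairs = length(d)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (non-parametric, n = %d):\n  bias %.4g [%.4g; %.4g], LOA [%.4g, %.4g]\n  Spearman rho = %.3f (p = %.3g)\n",
    x$n_pairs, x$bias_median, x$bias_q1, x$bias_q3, x$loa_low, x$loa_high,
    x$spearman_rho, x$spearman_p
  ))
  invisible(x)
}

#' Pupillary response between a baseline and a stimulation window
#'
#' The normalised pupil area is averaged over all present frames of each
#' window, each window mean is converted to an absolute diameter in mm (in
#' that order: average first, then convert), and the response is the
#' stimulation minus baseline diameter. At 30 fps the conventional windows
#' are a 900-frame (30 s) baseline and a 270-frame (9 s) segment at the
#' maximum tolerable stimulation intensity.
#'
#' @param a_norm per-frame dimensionless normalised pupil area.
#' @param baseline_window,stim_window inclusive 0-based frame ranges,
#'   `c(first, last)`.
#' @param ref_mm physical reference separation in mm (default 8).
#' @return list of class `response_result`: `baseline_mean_mm`,
#'   `stim_mean_mm`, `response_mm`, and the per-window frame counts used.
#' @export
pupillary_response <- function(a_norm, baseline_window, stim_window, ref_mm = 8) {
  n <- length(a_norm)
  win_mean <- function(win, label) {
    if (length(win) != 2 || win[1] > win[2]) {
      pk_contract_error(sprintf("%s window must be c(first, last)", label))
    }
    if (win[1] < 0 || win[2] >= n) {
      pk_contract_error(sprintf("%s window outside the series (0..%d)", label, n - 1))
    }
    v <- a_norm[(win[1]:win[2]) + 1]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      pk_insufficient_data_error(sprintf("%s window has no present frames", label))
    }
    list(mean = mean(v), n = length(v))
  }
  b <- win_mean(baseline_window, "baseline")
  s <- win_mean(stim_window, "stimulation")
  baseline_mm <- diameter_mm(b$mean, ref_mm)
  stim_mm <- diameter_mm(s$mean, ref_mm)
  structure(
    list(baseline_mean_mm = baseline_mm, stim_mean_mm = stim_mm,
         response_mm = stim_mm - baseline_mm,
         n_baseline = b$n, n_stim = s$n),
    class = "response_result"
  )
}

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf(
    "pupillary response: baseline %.3f mm, stimulation %.3f mm, response %+.3f mm\n",
    x$baseline_mean_mm, x$stim_mean_mm, x$response_mm
  ))
  invisible(x)
}
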