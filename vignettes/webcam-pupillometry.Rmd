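---
title: "Webcam pupillometry from keypoint tracks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Webcam pupillometry from keypoint tracks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilkit)
```

## The measurement problem

Standard infrared pupillometers cannot be used in every experimental
posture; a consumer webcam filming the eye at 30 frames/s can, and it
synchronises easily with stimulators and motion-capture equipment. A
markerless pose-estimation network tracks eight keypoints on the pupil
boundary (`P1`–`P8`, at roughly 45° spacing), the pupil centre (`P9`, unused
downstream), and four endpoints of a printed skin-mounted reference marker
(`S1`–`S4`); the `S2`–`S4` separation is physically calibrated (8 mm by
default). The network exports, per frame and keypoint, x/y pixel
coordinates and a likelihood in [0, 1]. `pupilkit` turns those tracks into
a calibrated pupil-diameter time series in millimetres and provides the
statistics used to validate the system and to quantify nociceptive
pupillary responses.

## Processing model

Each session passes through a fixed chain (`process_session()`):

1. **Coordinate smoothing.** A centred sliding median (window 3 frames,
   step 1) over each pupil keypoint's x and y series damps single-frame
   tracking jitter. Windows shrink at the series edges; missing values are
   skipped; an all-missing window stays missing.
2. **Robust ellipse fit per frame.** A conic
   $ax^2 + bxy + cy^2 + dx + ey + f = 0$ is fitted to the valid boundary
   points by algebraic least squares (SVD); the perpendicular (orthogonal)
   distance of each point to the fitted ellipse is computed; points with
   distance beyond $\mathrm{median} + k \cdot \mathrm{IQR}$ (default
   $k = 1.5$, the Tukey factor — the procedure's $k$ is a free parameter,
   so it is exposed in `robust_fit_config()` and echoed in the run log) or
   beyond $\alpha a_0$ (with $a_0$ the initial semi-major axis,
   $\alpha = 0.1$) are excluded, and the ellipse is refitted on the
   inliers. Fewer than 5 surviving points, or a non-elliptical fit at
   either stage, makes the frame invalid — a value, not an error. The pupil
   area is $A = \pi a b$ from the refined semi-axes.
3. **Area series cleaning.** Values outside
   $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 3.0\,\mathrm{IQR}]$ become missing
   (the asymmetry reflects that blink artefacts mostly deflate the fitted
   area), then gaps of at most 30 frames (~1 s) that are flanked by data on
   both sides are filled by linear interpolation. Longer gaps — sustained
   blinks or occlusions — remain missing, as do gaps touching the series
   ends (no extrapolation).
4. **Scale normalisation.** The per-frame reference length
   $L = \lVert S_2 - S_4 \rVert$ (px) is gated by manual plausibility
   thresholds (default ±50% of the session median), cleaned by a symmetric
   1.5 × IQR rule, and gap-interpolated. The dimensionless
   $A_{\mathrm{norm}} = A / L^2$ cancels uniform camera-scale changes, and
   $D = \mathrm{ref}_{mm} \cdot 2\sqrt{A_{\mathrm{norm}} / \pi}$ gives the
   equivalent-area circle diameter in mm.

The **pupillary response** to a stimulus averages $A_{\mathrm{norm}}$ over
a 900-frame (30 s) pre-stimulation baseline and over a 270-frame (9 s)
window at the maximum tolerable intensity, converts each window mean to mm
(average first, then convert), and takes the difference.

## Statistics

All analyses are non-parametric, with a Shapiro–Wilk test reported as a
normality gate (it never switches methods silently):

* `summarize_median_iqr()` — median [Q1; Q3] with **median-exclusive-halves
  quartiles**: the sample splits at the median (for odd n the median is
  excluded from both halves) and each quartile is the median of its half.
  This rule reproduces the bundled cohort's printed summaries
  (240 [215; 250] mA, 235 [120; 240] mA, 7 [7; 8]) exactly, which the
  interpolation-quantile alternative (also available) does not.
* `wilcoxon_signed_rank()` — zero differences dropped, mid-ranks for ties,
  $W = \min(W^+, W^-)$. For $n \le 25$ the two-sided p is exact over the
  full sign-assignment null with the actual mid-ranks, computed by
  subset-sum convolution (identical to enumerating the $2^n$ assignments);
  beyond that a tie-corrected normal approximation is used. On the bundled
  cohort this yields $p = 0.0078$ for the VAS pairs and $p = 0.0625$ for
  the current pairs.
* `bland_altman_nonparametric()` — bias as the median difference with
  [Q1; Q3], limits of agreement as the 2.5th/97.5th percentiles
  (interpolation quantiles), plus Spearman correlation. The Spearman p is
  exact for untied samples of $n \le 10$ and uses the t-approximation
  otherwise (tied small samples included: there is no exact tie-aware null
  available, and all realistic uses here have $n > 10$).

## The synthetic session generator

`generate_session()` emulates what the tracking network emits, with known
ground truth: a trapezoidal true-diameter profile (baseline plus
rise/plateau/fall dilation events); the true ellipse preserving the
equivalent-area circle ($a b$ fixed by the diameter, axis ratio free, so
any eccentricity must reproduce the same diameter); boundary keypoints at
45° parameter spacing plus isotropic Gaussian noise; blinks (Poisson
onsets) blanking all pupil keypoints; sporadic gross keypoint
displacements with likelihood < 0.2; and a slow sinusoidal uniform scale
drift multiplying every coordinate, with the reference endpoints placed so
$\lvert S_2 - S_4 \rvert$ is exactly 8 mm at the instantaneous scale.
Draws occur in a fixed order from a single seeded stream, so sessions are
bitwise reproducible.

Defaults are chosen once as realistic study conditions: 30 fps, 20 px/mm,
baseline diameter 5.7 mm, axis ratio 0.9, noise 0.5 px, 10 blinks/min of
200–400 ms, outlier shift 30 px. What the generator does **not** emulate:
pupil light-reflex dynamics, eyelid geometry, specular reflections,
non-uniform scale changes (head rotation), or correlated tracking error —
so passing recovery tests demonstrate the *post-processing* chain, not the
tracking network.

## Numerical choices

* **Conic fit conditioning and equivariance.** Points are centred on their
  centroid and scaled to unit RMS radius before the SVD, with the $xy$
  column weighted by $\sqrt 2$ so the unit-norm constraint is rotation
  invariant; the conic is mapped back afterwards. Beyond conditioning,
  this makes the fit commute *exactly* with translation, rotation and
  uniform scaling of the input — which is what guarantees the pipeline's
  end-to-end scale invariance (measured ~1e-13 on noisy sessions) rather
  than only approximately, as the raw-coordinate fit would.
* **Point-to-ellipse distance.** True orthogonal distance (algebraic
  residual is biased by eccentricity and offered only as a config switch):
  the point is folded into the first quadrant of the ellipse frame, the
  nearest-point parameter is bracketed on a 17-point grid over
  $[0, \pi/2]$ and polished by safeguarded Newton iteration (step
  tolerance 1e-12, at most 50 iterations). The grid stage avoids the
  classical traps (points near the centre or inside the evolute, where
  naive polar-angle initialisation converges to a maximum).
* **Quantiles.** Interpolation (type 7) quantiles inside the IQR gates and
  for the limits of agreement; the exclusive-halves rule for reported
  median-IQR summaries. Both choices are configurable where they matter.
* **Ties and degeneracies.** IQR = 0 collapses the gate bounds to
  [Q1, Q3], which remain inclusive; exclusion comparisons are strict.
  Constant difference vectors make the Wilcoxon test and Spearman
  correlation degenerate — both raise classed errors rather than return
  fabricated values.

## Design decisions on genuinely open points

* **Smoothing vs pooling.** The source procedure describes both
  per-keypoint median smoothing and pooling of up to 24 markers over a
  3-frame window without stating their composition. The default pipeline
  smooths and fits each frame's 8 points; `pool_frames = TRUE` fits the
  pooled window union instead. On clean synthetic data the two agree to
  well under 2% in diameter.
* **Reference endpoint pair.** `S2`–`S4` is the calibrated, most stable
  pair and is the default; the pairing is configurable because labelling
  conventions vary.
* **Likelihood filtering** is off by default (long sessions with
  stimulation-induced movement make fixed thresholds impractical), but a
  threshold can be set; points below it are treated as missing before any
  processing.
* **Frame indexing** accepts any strictly increasing contiguous index
  column and re-bases to 0; the frame rate is configuration (default 30),
  since the CSV carries no timing.

## Known limitations

* **Gross-outlier exclusion at the single-frame level is unreliable.** An
  unconstrained algebraic conic fit on 8 points has 5 degrees of freedom
  and *absorbs* 1–2 grossly displaced points (high leverage): the
  outlier's distance to the initial fit is a small fraction of its true
  displacement and overlaps the clean points' distances, so no distance
  threshold — including the $\alpha a_0$ rule — separates them reliably.
  Reliable exclusion would need consensus search (RANSAC/LTS-style),
  which is deliberately out of scope. In practice the sliding median
  removes single-frame outliers before fitting and the area-series gate
  catches the residue, so end-to-end diameter recovery on noisy sessions
  with 5% injected outliers reaches a mean absolute error of ~0.02 mm;
  the per-frame fitter alone should not be relied on to label outliers.
* The reference cancels only **uniform** scale change; head rotation needs
  a two-dimensional reference and is out of scope.
* Interpolated stretches are genuine unknowns bridged linearly; analyses
  sensitive to fast dynamics should exclude `quality_flag == "interpolated"`
  frames.

## Problem sizes used in the checks

The bundled test-suite and acceptance script run entirely on synthetic
sessions: recovery checks use 18–20 seeded sessions of 1200–1800 frames
(40–60 s at 30 fps) at 20 px/mm with 0.5 px noise, blinks, 5% outliers and
3–5% scale drift; the Wilcoxon exactness checks enumerate all sign
assignments for n ≤ 12 against the convolution implementation and measure
the empirical type-I error over 10,000 null replicates at n = 9.
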