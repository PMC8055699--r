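---
title: "Measuring iris surface smoothness in AS-OCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring iris surface smoothness in AS-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irissmooth)
```

## The index

Iris atrophy in unilateral anterior uveitis blunts the crypts of the
anterior iris surface, making the affected iris visibly smoother than the
fellow eye's. The smoothness index condenses that impression into one
number per iris side. Given the most peripheral and most central points of
the anterior iris border on a horizontal B-scan,

$$\mathrm{SI}_{side} = \frac{BL}{AL}, \qquad
\mathrm{SI}_{overall} = \frac{BL_n + BL_t}{AL_n + AL_t},$$

with $BL$ the Euclidean chord between the two landmarks and $AL$ the length
of the border path between them. Since a chord never exceeds the curve it
subtends, $0 < \mathrm{SI} \le 1$, with equality only for a straight
border. The overall SI is the *mediant* of the two side ratios and
therefore always lies between them. Note that the source description of the
automated measurement attaches the shortest-path construction to $BL$ and
the Euclidean distance to $AL$; that assignment is geometrically impossible
(it would force SI $\ge$ 1 everywhere) and this package implements the only
consistent reading, which also matches the manual-measurement definition:
chord in the numerator, along-border length in the denominator.

The pipeline is deliberately semi-automated: landmark choice ("most
peripheral", "most central") is operator judgment, and the four points are
opaque inputs here. Everything after the click is deterministic.

## Pipeline stages and their parameters

### Preprocessing

* **Crop window** — `preprocess_config(crop_window=)`, 0-based half-open
  `(row_start, row_stop, col_start, col_stop)`. Native CASIA2 exports are
  1000×1414; the conventional analysis frame is 629×1102
  (`casia2_crop_window()`). Only the output size is fixed by convention, so
  the offset is configurable; `NULL` (default) analyzes the full input.
* **Histogram matching** — classic 256-bin CDF inversion against a
  reference histogram, ties broken toward the lower output level, so the
  mapping is monotone and idempotent to within one gray level. A constant
  image cannot be matched meaningfully and maps to the reference median
  with a warning.
* **Complement** — `v -> 255 - v`, so the bright iris band becomes the dark
  class, matching the segmentation polarity below.

**A caveat that shapes the defaults.** Because matching is a monotone
remap, the matched image inherits the *reference's* histogram; any
threshold computed afterwards is, in effect, a quantile threshold at the
reference's tissue fraction. Matching is therefore only sound when the
reference shares the image's approximate iris/background proportions — in
practice, when it comes from the same imaging setup, which is exactly how
the original protocol chose its reference ("the image with better quality
and contrast"). The package ships a reproducible stand-in: the canonical
synthetic phantom (crypt amplitude 6 px, speckle 0.10, blur 1 px) rendered
at the native geometry (`default_reference_histogram()`), or at any other
geometry via `reference_histogram_for()`. The canonical reference carries
speckle 0.10 rather than 0 deliberately: a noise-free phantom has a spiky
two-mode histogram and matching to it posterizes the image.

### Segmentation

* **K-means binarization** — Lloyd's algorithm on the 256-bin histogram
  with $K = 2$ (iris border vs background), centroids initialized at the
  10th and 90th percentile intensities, stopping when both centroids move
  less than `tol` (default 0.5 gray levels) or after `max_iter` (100).
  Histogram-domain K-means is deterministic — no random restarts — which is
  what "adaptive" buys here: the cut adapts to each image's histogram
  without any seed. Foreground polarity defaults to the darker cluster
  (correct after the complement).
* **Morphological cleanup** — closing with a digital disc of radius
  `closing_radius` (default 2 px), removal of 8-connected foreground
  components smaller than `min_area` (default 50 px), filling of
  4-connected background holes smaller than `min_area`. The disc uses the
  slightly dilated rasterization $d^2 \le r^2 + 1$: a strict Euclidean disc
  of radius 2 cannot re-bridge a 1-px break between collinear 1-px-thin
  border fragments (the erosion step re-opens it), while the digital disc
  closes exactly such defects — which is the point of this stage. The
  recipe is idempotent.
* **Border extraction** — keep the largest 8-connected components (ties by
  topmost-then-leftmost first pixel) and mark foreground pixels with a
  4-neighbour in background. The complementary 8/4 connectivity pair avoids
  the usual topological paradoxes. A horizontal scan through the pupil
  shows nasal and temporal iris as two separate regions, so the full
  pipeline keeps the two largest components, one per side.

### Length measurement

* **Snapping** — clicks are moved to the nearest border pixel
  (spacing-weighted Euclidean distance, ties by smaller row then column)
  within `snap_radius` (default 10 px — generous for click error, small
  against iris scale). Coinciding snapped endpoints raise an error rather
  than silently reporting SI = NaN.
* **Geodesic length** — shortest 8-connected path inside the border mask,
  step weights $s_y$, $s_x$, $\sqrt{s_y^2+s_x^2}$, computed by seeding a
  geodesic distance transform at each endpoint and taking the global
  minimum of the sum of the two transforms; an independent Dijkstra oracle
  (igraph, in the test suite) agrees to $10^{-9}$.
* **Arc-length correction** — the raw 8-connected path cost systematically
  *overestimates* continuous curve length (up to ~8% for slopes near
  22.5°; ~6% already at slope 0.2). Empirically this depressed measured SI
  by 0.03–0.06, three times the package's accuracy target. The default
  `estimator = "corrected"` therefore applies the Vossepoel–Smeulders
  chain-code estimator to the geodesic path,
  $0.980\,n_{axial} + 1.406\,n_{diag} - 0.091\,n_{corner}$ (isotropic
  spacing only; anisotropic spacing falls back to raw weights), which
  brought the SI error under 0.005 across the validation grid.
  `estimator = "raw"` gives the uncorrected cost. Because a continuous
  border cannot be shorter than its chord, $AL$ is floored at $BL$, which
  also pins the flat-border case to SI = 1 exactly.
* **Units** — with the default spacing `(1, 1)` lengths are in pixels; SI
  is unit-free under isotropic spacing. Supplying anisotropic physical
  spacing makes the lengths physical but note the ratio then depends on
  orientation.

## The synthetic world

`synthetic_iris_spec()` renders a bright band (tissue level 180) on a dark
background (level 30), split by a 180-px pupil gap into two 420-px sides at
the native 629×1102 frame. The anterior border follows a parametric crypt
curve — a sinusoid by default, or a sum of Gaussian pits — with peak depth
`crypt_amplitude` and `crypt_frequency` crypts per side (default 8, giving
crypt widths of ~50 px, and analytic overall SIs of 1.00/0.97/0.92/0.86 at
amplitudes 0/6/10/14 px, spanning the clinically reported 0.77–0.92 range).
The crypt phase is randomized per image (seeded) so that amplitude, not
pixel layout, carries the signal. Speckle is multiplicative log-normal
(mean 1, σ = `speckle_sigma`, default 0.10) — the standard first-order OCT
noise model — followed by a Gaussian PSF (`blur_sigma`, default 1 px).
Rendering is byte-deterministic in `(spec, seed)`.

True SI comes from `analytic_si()`: chord over
$\int_a^b \sqrt{1 + f'(x)^2}\,dx$ by adaptive quadrature (relative
tolerance $10^{-8}$, summed over subintervals because the multi-crypt
integrand is oscillatory), cross-checked in the tests against a $10^6$-point
trapezoid sum.

`generate_cohort()` emulates the study design: `n_subjects` per group, two
eyes each. Per-subject base SI is drawn from N(0.85, 0.02) (the reported
healthy automated means are 0.84–0.86), an eye-level jitter of SD 0.0106 is
added — calibrated so the control group's expected absolute inter-eye
difference is 0.012, the reported control value — and affected eyes are
shifted by `fu_effect` (default 0.03, the reported FU-group inter-eye
difference). Target SIs are converted to crypt amplitudes by inverting the
analytic SI (`amplitude_for_si()`, bisection). The generator shifts
affected eyes *down* in SI (amplitude up); the clinical direction is the
opposite (atrophy raises SI), but the inter-eye statistic is an absolute
difference, so the sign is immaterial and the stated construction is kept.

**What a green test does and does not establish.** The phantom reproduces
the geometry that the SI measures — a band with controllable-tortuosity
upper border, speckle, blur, two sides — so it validates the measurement
chain end to end against analytic truth. It does not emulate device
artifacts, specular reflections, angle structures, iris vessels, posterior
border texture, or operator variability in landmark choice; agreement with
the clinical numbers on real scans is an optional benchmark, not something
these tests can establish.

## Agreement statistics

`bland_altman()` reports mean difference and mean ± 1.96 SD (n−1
denominator) limits of agreement. `icc_two_way_random()` implements
ICC(2,1) — two-way random effects, absolute agreement, single measure —
from the ANOVA mean squares, with the McGraw–Wong F-based 95% CI. The
source reports only "two-way random ICC"; ICC(2,1) is the conventional
reading for single-rater reliability, and the form is recorded in every
report so the choice is auditable. Zero between-subject variance returns
ICC 0 with a warning; error-free ratings return a degenerate CI at the
point estimate. `inter_eye_difference()` summarizes per-subject
$|SI_{OD} - SI_{OS}|$; group comparison is left to stock rank-sum routines.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)`, row 0 at the top, half-open
  windows, everywhere.
* Histogram-matching ties break toward the lower output level; the
  K-means threshold is the centroid midpoint, and where the inter-mode
  histogram gap is empty the within-class SS is flat, so only the induced
  partition of occupied levels is well-defined.
* Component-size ties in border extraction break by first pixel in
  row-major order.
* Constant images: matching warns and maps to the reference median;
  binarization refuses ("single gray level").
* Disconnected landmark pairs raise a connectivity error naming the
  endpoint; per-image failures in batch mode are logged and skipped.
* RNG state is pushed and popped around all generators, so library calls
  do not perturb the caller's stream; cohort eye seeds are derived from the
  master seed and kept below $2^{31}$.

## Known limitations

* TIFF input is not supported in this build (no TIFF reader among the
  package's dependencies); PNG, JPEG and PGM are.
* The chain-code correction assumes isotropic pixel spacing; with
  anisotropic spacing the raw (overestimating) weights are used.
* Histogram matching against a reference with a very different tissue
  fraction biases the segmentation (see above); supply a geometry-matched
  reference in that case.
* The measured border is the outer boundary of the binarized band; if the
  binarization captures a thick band versus a thin border ridge, both
  reduce to the same boundary curve, but sub-pixel border localization is
  not attempted.
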