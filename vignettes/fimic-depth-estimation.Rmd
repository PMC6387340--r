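---
title: "Depth estimation for Fourier integral light-field microscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth estimation for Fourier integral light-field microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fimicdepth)
```

## The imaging model

A Fourier integral microscope (FiMic) places the microlens array at the
Fourier plane of the objective instead of the image plane, so the sensor
records perspective views of the sample directly: one central elemental
image surrounded by six peripheral ones on a hexagonal grid. Opposite views
form three epipolar axes at 0°, 60° and 120°; a point at depth appears
displaced between views along its axis by a disparity of a few pixels up to
tens of pixels. Compared with ordinary plenoptic cameras the light field is
*sparse* — 7 views with large baselines — so resampling the views onto a
rectangular grid would destroy them, and the package works on the hexagonal
geometry directly.

Three closed forms summarize the optics. With `Mn` microlenses across the
aperture-stop diameter, emission wavelength $\lambda$ and numerical aperture
NA, the lateral resolution limit is $r = Mn\,\lambda / (2\,\mathrm{NA})$ and
the depth of field is $\mathrm{DOF} = \tfrac54 \lambda\, Mn^2 /
\mathrm{NA}^2$; they trade off through $Mn$ and obey $5 r^2 / \mathrm{DOF}
= \lambda$ identically, which the test suite uses as an algebraic oracle.
Shifting every peripheral view $s$ pixels toward the image center and
averaging synthesizes a plane refocused at
$z_R(s) = s \cdot (f_{MO}^2 f_L f_2 / f_1^2) \cdot (\delta / p)$,
linear and odd in $s$. `refocus_depth()` evaluates this magnification chain
as published, with every length reduced to micrometres; the printed factor
is dimensionally heterogeneous, so the function should be read as the
instrument's calibration formula rather than a first-principles derivation,
and no test anchors it to a particular absolute depth.

## The two depth cues

**Correspondence.** For each of the six central–peripheral pairs a cost
volume over candidate disparities $d$ is built along the pair's epipolar
direction: a truncated absolute difference (robust to outliers, truncation
$\tau$) mixed with a census-transform Hamming cost (invariant to monotone
intensity changes) through a weight $\alpha_c$. Window sums use
adaptive support weights
$w \propto \exp(-(|\Delta I|/\sigma_c + \|o\|/\sigma_d))$, normalized to sum
to one per window; normalization makes $\tau$ directly interpretable and
slices comparable across window sizes. The printed form of the weight
formula is ambiguous about the sign of the distance term (read literally it
would *up-weight* distant pixels); the package uses the bilateral-style
decay of the adaptive-support-weight literature. The six pair volumes are
merged per pixel with the failure-prediction weights (below) and
guided-filtered slice by slice with the central image as guide.

**Defocus.** The focal stack is built by count-normalized shift-and-sum:
pixels that a shifted view cannot cover are excluded from the average
rather than zero-filled, which avoids darkened borders. The defocus cost of
shift $s$ compares the central image with the refocused plane through
$\alpha_d\,\mathrm{TAD} + (1-\alpha_d)(1-\mathrm{NCC})/2$; the NCC is
computed from adaptive-weighted moments and maps to a dissimilarity so that
lower is better in both volumes, and windows with negligible variance in
either image return NCC = 0 (dissimilarity 0.5), flagging texturelessness
instead of amplifying noise. The focal-stack shifts equal the disparity
labels, so the two volumes share one label grid and can be mixed slice by
slice.

Fractional shift components on the 60°/120° axes (cos 60° = ½) are handled
by bilinear interpolation per shift; the views themselves are never
resampled. Any candidate that samples outside the frame is masked and the
merge weights renormalize over the remaining views.

## Priors

* **Frequency map** — $|I * (g(\sigma_1) - g(\sigma_2))|$, a
  difference-of-Gaussians band response, quantized into `Fs = 3`
  equal-population (quantile) levels. Quantiles rather than fixed thresholds
  make the levels robust to global contrast. Defaults
  $\sigma_1 = 1, \sigma_2 = 2$ px select the texture band that matters at
  the matching window scale.
* **Failure-prediction maps** — matching along an epipolar axis cannot fix
  structures aligned with that axis. For each axis an edge-along-axis
  detector is obtained by steering the Sobel derivative pair to the axis
  direction; this steering is exact for first-order derivative kernels and
  exactly equivariant under rotation, which is why it is used instead of a
  numerically rotated kernel. The per-axis weight is the normalized
  complement of the smoothed detector magnitude: per pixel the three weights
  sum to 1, and a featureless neighbourhood gives ⅓ each.
* **Matte** — fluorescence scenes have a dark background that records no
  signal; any depth estimated there is noise. A three-class trimap
  (two-threshold Otsu by default) feeds an affinity-based alpha matte
  (matting-Laplacian on 3×3 windows, grayscale color-line model, sparse
  direct solve) whose hard constraints are honoured exactly. The matte mask
  restricts evaluation, gates the smoothness prior and selects which pixels
  vote in superpixel histograms. The matting is engaged automatically only
  when the trimap's background class is both large (≥ 20 % of pixels) and
  genuinely dark (mean below 0.15), so textured scenes are not masked by
  accident.

## Aggregation

**Multi-scale.** The volumes are rebuilt at scales 1, 2 and 4 (block-mean
downsampling, per-scale disparities $d/k$ so the label count is constant),
upsampled back, and blended per pixel: a pixel whose frequency level is
highest trusts the full-resolution volume with weight $\gamma_1$, adjacent
scales get $\gamma_2$, the rest $\gamma_3$, with
$1 \ge \gamma_1 \ge \gamma_2 \ge \gamma_3 \ge 0$, defaults
$(0.6, 0.3, 0.1)$; the applied weights are renormalized per pixel, so equal
$\gamma$s reduce to the plain three-scale mean.

**Superpixels.** A grayscale SLIC segmentation (grid-seeded local k-means,
connectivity enforced; deterministic) groups similar pixels; inside each
superpixel the winner-takes-all label histogram is lightly smoothed, its
strongest `Np = 3` local maxima are kept (ties to the lower label), and each
peak is widened by a tent of half-width $\sigma = 3$ labels:
$z(t) = \max_i \max(0, 1 - |t - \mathrm{peak}_i|/\sigma) \in [0,1]$.
The volume is shaped by adding $\rho\,(1 - z(t))$ with $\rho = 0.2$ — an
additive, non-negative penalty, so shaping never lowers a cost and
$\rho = 0$ is the identity. The printed form of the peak-widening sum is
sign-asymmetric and would cancel between symmetric peaks; the tent
maximum implements its stated purpose (widening each peak toward its
neighbours, $z = 1$ exactly at peaks). Shrinking the superpixels and
setting `Np = 1` with a narrow tent recovers a single-depth-per-superpixel
behaviour.

## Fusion and optimization

Winner-takes-all maps of the two shaped volumes give a normalized
disagreement map $\mathrm{Mad} = |l_{def} - l_{cor}|/K$ (default
$K = L - 1$). Where the cues agree exactly ($\mathrm{Mad} = 0$) the pixel
becomes a ground control point: a penalty linear in the label distance from
the agreed label, scaled by $\beta = 0.5$, anchors it. The data term mixes
the volumes per pixel with Mad-dependent weights. Both conventions are
implemented: the `as_printed` mix weights the correspondence volume by Mad,
and the `as_prose` mix weights the *defocus* volume by Mad, i.e. the
correspondence cue dominates where the cues (nearly) agree and the defocus
cue takes over only under large disagreement. The pipeline defaults to
`as_prose`: on the phantom suite the printed mix routes almost all weight
to the defocus volume (the weaker, lower-resolution cue) even where both
cues concur, and measurably falls behind a naive WTA baseline, while the
prose convention beats that baseline on every suite scene — matching the
motivation that correspondence is the more accurate cue and defocus the
more robust fallback.

The depth map minimizes
$E = \sum_p E_{data}(p, l_p) + \lambda \sum_{(p,q) \in N_4} |l_p - l_q|$.
The smoothness weight $\lambda$ (default 0.05) is chosen so the two terms
have comparable magnitude on the phantom suite given the window-normalized
cost scale; results were insensitive across a factor-2.5 range. Because the
untruncated linear prior is convex in the label difference, the global
minimum is computed *exactly* by a single multi-layer min cut over
$N (L-1)$ binary variables $x_{p,k} = [l_p \ge k]$; a truncated-linear
prior (still a metric, no longer convex) falls back to iterated
α-expansion, each move solved exactly by one min cut from a winner-takes-all
initialization. The choice of the exact route as default was made after
observing that correct α-expansion (its moves verified against subset
enumeration) still terminates in move-space local minima on a noticeable
fraction of random instances, while the convex prior admits exact
minimization at the same asymptotic cost. Both routes assert on every run
that the final energy does not exceed the initialization energy, and the
per-sweep energies are logged in the intermediates manifest. The min-cut
backend is a Boykov–Kolmogorov augmenting-path solver written for this
package (grid graphs of ~10⁵–10⁶ nodes), validated in the test suite
against an independent max-flow implementation on random graphs.
Smoothness edges that touch matted-out pixels are dropped: background
pixels carry no photometric signal, and letting their (meaningless) labels
pull on foreground structures measurably degrades thin objects.

Post-filtering applies a weighted median on the label image (integer
weights 1–8 quantized from guide affinities in a 5×5 window) followed by a
guided filter on the disparity image, then re-quantizes to the label grid.
Constants pass through both filters unchanged; single-pixel outliers are
removed; depth steps stay aligned with guide edges.

Tie-breaking everywhere is deterministic: any argmin returns the lowest
label index, so a degenerate (all-equal) cost curve yields label 0 and the
whole pipeline is bytewise reproducible for fixed inputs and configuration.

## The synthetic scene generator

`generate_scene()` renders a textured central view over a known disparity
field and backward-warps it into the six peripheral views along the
hexagonal directions (bilinear sampling). Five phantom families cover the
behaviours that matter: a fronto-parallel plane (pure recovery), a tilted
plane (sub-label structure, quantization floor ≈ 0.25 labels on an integer
grid), a depth step (discontinuity preservation), fluorescent-style fibers
over a dark background (thin structures, matting, Poisson–Gaussian noise),
and disks at distinct depths (occluding boundaries). The suite
(`phantom_suite()`) fixes five such scenes at 256×256 with disparities in
[0, 8] — single-digit label counts keep the discrete optimization fast
while exercising every stage — with per-scene seeds derived from one base
seed; identical spec and seed reproduce identical bytes. Noise defaults
(read noise σ = 0.01–0.02, shot noise at ~200 photons per unit intensity on
the fibers scene) reflect moderately exposed fluorescence acquisitions.

What the generator does *not* emulate: true occlusion rendering (backward
warping duplicates the foreground texture across depth edges instead of
revealing hidden background), defocus blur within each view, the microscope
PSF, and vignetting. Passing the suite therefore demonstrates the
correctness and robustness of the matching, aggregation and optimization
machinery on parallax-consistent inputs — not photometric fidelity to any
particular instrument. The evaluation metric is the mean (and standard
deviation) of the absolute difference between estimated and true disparity
over the matte/object mask.

## Numerical choices and degenerate inputs

* Borders: window operations use replicate padding; shifted samples outside
  the frame are masked and merge weights renormalize; if every view is
  invalid at a pixel the merge falls back to the unweighted mean of the
  edge-clamped costs, so volumes never contain NaN.
* A constant image yields: frequency level 0 everywhere, axis weights ⅓,
  an all-background trimap, zero cost curves, and a label-0 depth map (tie
  rule) — asserted end to end as the zero-parallax contract.
* The matting system is solved with a sparse Cholesky factorization of the
  (SPD) regularized Laplacian; fully constrained trimaps bypass the solver.
* Quantile quantization puts ties in the lower level, so a flat region can
  never occupy a high-frequency level.
* Equal-population binning, SLIC seeding and all argmin tie-breaks are
  deterministic; no stage draws random numbers at run time.

## Problem sizes

Unit tests run on 9×9 oracle instances and 32–128 px scenes; the
acceptance checks run the full pipeline at 256×256 with 9 labels (about
40 s per scene on one core, the correspondence volume dominating), and the
optimality oracle enumerates all 3⁹ labelings of 3×3 instances. These sizes
were chosen to exercise every code path at interactive turnaround; nothing
in the implementation is specific to them, and the cost-volume kernels and
min-cut solver are compiled code sized for megapixel inputs.

## Known limitations

* Occlusions are not modeled; depth edges inherit a ~1-pixel halo from the
  window costs, and the defocus cue has intrinsically lower depth
  resolution than correspondence (shallow minima), which is why the fusion
  leans on correspondence wherever the cues agree.
* Disparities are integer labels; no sub-label parabola refinement is
  performed (out of scope), so continuously varying surfaces carry a
  ~0.25-label quantization floor.
* The pipeline is single-channel; RGB input is reduced to luma on load.
* Matting assumes a dark, near-uniform background; bright backgrounds
  disable it (by design) rather than producing a partial matte.
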