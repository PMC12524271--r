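---
title: "Methods: stereo keypoint morphometry and mass estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo keypoint morphometry and mass estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereofish)
```

## The measurement model

stereofish implements a non-contact pipeline for measuring free-swimming
fish with a rectified stereo camera. A keypoint detector (external to this
package; its building blocks are implemented structurally, see below)
localizes four anatomical landmarks per fish in the left image: the head
point, the tail point (tail fin excluded), and the upper- and lower-width
points at mid-body. Given a per-keypoint depth $z$ — from a stereo matcher,
a depth camera, or the synthetic generator — each pixel $(u, v)$ is
back-projected through the inverse pinhole relation

$$X = \frac{(u - u_0)\,z}{f_x}, \qquad Y = \frac{(v - v_0)\,z}{f_y}, \qquad Z = z,$$

into the left-camera frame. Body length is the 3D Euclidean distance
between head and tail; body width the distance between the two width
points. Both are raw chords: no projection onto a body axis and no
arc-length correction is applied, so a bent body yields a chord that
underestimates the true midline length (see "Known limitations").

Mass is predicted from $(\mathrm{length}, \mathrm{width})$ in centimeters
by a random-forest regression implemented natively in the package:
bootstrap-resampled CART trees with variance-reduction (SSE) splits
restricted to `mtry` random features per node, predictions averaged
arithmetically over trees. The biological structure the forest exploits is
allometric: mass scales approximately as $a \cdot L^b$ with $b \approx 3$.

### Conventions

* Meters internally; centimeters (sizes) and grams (masses) at reporting
  boundaries, CSV output rounded to 2 decimals (cm) / 1 decimal (g).
* Continuous pixel coordinates, origin at the top-left corner, x right,
  y down, pixel centers at integer coordinates — including annotation I/O.
* All reconstructed points live in the left-camera frame. Extrinsics enter
  only when projecting into the right camera; for a rectified horizontal
  rig with baseline $B$, disparity obeys $d = f_x B / Z$.
* Lens distortion is not modeled; inputs are assumed rectified. The
  calibration loader warns if distortion coefficients are present.
* Whether keypoint depth should be read at the exact pixel or pooled over
  a neighborhood is not standardized by detector pipelines; `depth_at()`
  exposes both (nearest pixel, default, and a median over a k×k window).

## Mass-model parameters

The forest defaults are conventional for random-forest regression and all
exposed: `n_trees = 100`, `mtry = 1` (of 2 features — the random-subspace
step is nearly degenerate with two predictors but still decorrelates
trees), `min_samples_leaf = 2`, unlimited depth, bootstrap on. Candidate
split thresholds sit at midpoints of sorted unique feature values; ties are
broken toward the lowest feature index, then the smallest threshold, making
the fit fully deterministic given data order and seed. Training uses
measured (caliper) sizes; prediction uses stereo-estimated sizes.
`compare_regressors()` evaluates the native forest against registered
competitors on a single shuffled 80/20 split — no cross-validation protocol
is imposed, and repeated splits are recommended when margins are thin
(over the 8–19 cm size range a plane fits the cubic allometry closely, so
the forest's advantage over a linear baseline is a mean effect across
splits, not a per-split guarantee).

Per-fish estimates are reported per frame by default; optional mean
aggregation across frames of one fish is available but off, since repeated
per-fish estimates carry independent posture error and downstream users
may want them unpooled.

## Evaluation metrics

Object keypoint similarity is computed as

$$\mathrm{OKS} = \frac{\sum_i \exp\!\left(-d_i^2 / (2\,s^2\sigma_i^2)\right)\,[\nu_i > 0]}{\sum_i [\nu_i > 0]}$$

with the scale taken as $s^2 = \text{box area}$ (the COCO convention; the
alternative printed reading that squares the area differs only by a
reparametrization of $\sigma$). Fish-specific per-keypoint $\sigma_i$
values are not published anywhere, so the package defaults to
$\sigma_i = 0.05$ for all four keypoints and makes them configurable —
they must be explicit for OKS numbers to be reproducible.

Matching is greedy in descending score (COCO-style), one-to-one, each
detection claiming the unmatched ground truth of highest similarity above
the threshold; it is deliberately not optimal assignment, and is tested
against an independently coded reference matcher. Average precision
defaults to the all-point precision-envelope integral, with the 101-point
COCO sampling available for parity with external tooling; mAP50-95
averages thresholds 0.50 to 0.95 in steps of 0.05.

Two R² conventions circulate for regression quality; the default here is
the coefficient of determination $1 - SS_{res}/SS_{tot}$, with the squared
Pearson correlation available as `r2_mode = "pearson"`. They coincide for
an OLS fit evaluated in-sample and differ otherwise.

## The synthetic generator

Every downstream stage is testable without video data because the
generator produces ground-truthed scenes that emulate the acquisition
setting: a rectified 1920×1080 pair, 120 mm baseline, focal length 1050 px
(a consumer stereo depth camera at full HD), fish at 0.5–2.5 m. Fish are
drawn from four size classes with length ranges (cm) L 16.9–18.6,
M-L 13.1–15.5, M-S 10.0–12.4, S 8.1–9.1 — spanning the packaged real
measurements — width as length times a Normal(0.225, 0.015) ratio (the
ratio scatter observed in those measurements), and mass from
$a L^b e^\varepsilon$ with defaults $a = 0.018$, $b = 3$,
$\varepsilon \sim N(0, 0.1)$, fit by eye to the packaged length/mass
pairs (e.g. 17.65 cm ↔ 106.6 g).

Body bend is modeled as a circular arc in the sagittal plane — the
simplest shape exhibiting the chord-vs-arc error of a swimming fish — with
curvature drawn half-normally (sd 0.5 m⁻¹) and capped below self-
intersection; width points sit perpendicular to the midline at mid-body,
so width is bend-invariant by construction. Orientation is limited to
±0.3 rad of tilt, mirroring annotation practice that keeps only
near-parallel fish.

Environmental condition presets map the five acquisition strata to noise
levels (invented, documented, overridable): keypoint jitter σ from 0.3 px
(clear water, low density) to 1.5 px (low light), relative depth noise
0.1%–1%, per-keypoint dropout 0–10%, false positives 0–5% per true fish.
The presets are ordered so severity increases monotonically, and the test
suite verifies that size-estimation error respects that ordering.

All randomness flows from one master seed through named substreams
(population, pose, noise), so each stage is independently reproducible.

What the generator does **not** emulate: pixels (no appearance, texture,
blur or photometric effects — condition presets act on annotations, not
images), refraction at the housing port, occlusion geometry between fish,
correlated depth errors from stereo-matching failures, and detector-
specific error structure. Passing tests therefore demonstrate the
correctness of the geometry, measurement and evaluation mathematics under
controlled noise, not detector performance on real imagery.

## Numerical choices

* Split thresholds at midpoints; deterministic tie-breaks (lowest feature,
  smallest threshold). Degenerate nodes (constant response, too few
  samples) become leaves.
* Forest predictions are means of leaf means, hence always bounded by the
  training response range.
* OKS is undefined with no visible ground-truth keypoints and raises a
  typed error rather than returning 0.
* An empty precision-recall curve yields AP 0 with a warning; zero ground
  truths make recall undefined and raise an error.
* `estimate_sizes()` never guesses: a fish missing any of the four visible,
  depth-resolved keypoints is skipped with a reason code
  (`invisible_keypoint`, `missing_keypoint`, `unresolved_depth`) and
  logged; a width exceeding length warns but is reported.
* Rotation matrices are validated orthonormal with determinant +1 at
  tolerance 1e-9; reflections are rejected.

## Architecture module

The detector's building blocks are implemented as plain-array forward
passes sufficient for structural contracts — training is out of scope.
"Deep convolution" is realized as depthwise convolution. In the gated
block, the stem's output is split into three equal branch widths (gate,
spatial, identity); the sigmoid gate weights both content branches before
concatenation, which keeps the gating elementwise-valid while honoring the
three-way decoupling; the residual add requires matching channels in
strict mode, with an optional 1×1 projection otherwise. Kernel sizes,
hidden widths, activation (SiLU) and normalization (batch norm) follow
YOLO-family convention and are configurable, since the published block
descriptions are topological, not dimensional. Shape flow at 640×640 is
validated symbolically; numeric forwards run on small maps. Parameter
counts are exact closed-form sums and `inspect_model()` reports the total
— published counts for comparable lightweight detectors sit near 2.9 M,
but widths being unpublished, this comparison is diagnostic only.

## Problem sizes used by the test suite

Unit and property tests run at sizes chosen for sharp discrimination at
interactive runtimes: 1000-point geometry round trips, 10-seed × 100-fish
noise-monotonicity sweeps, 50 randomized metric scenes against the
independent reference, 20-seed × 144-fish mass-model recovery (matching
the 144 measured fish of the packaged study data), and 200-fish end-to-end
recovery scenes.

## Known limitations

* Chord-based length: bent fish are underestimated by chord-vs-arc; the
  generator reproduces the effect and tests assert its direction, but no
  correction is applied (arc-length correction and girth features are out
  of scope).
* Error budget of 3D recovery scales with $Z / f_x$: at the far end of the
  default 0.5–2.5 m range, sub-millimeter recovery is only achieved in the
  low-jitter regimes; with combined pixel jitter and per-keypoint depth
  noise the residual size error is dominated by the depth term, and width
  (a small quantity) is proportionally more affected than length.
* The packaged validation tables carry printed-precision predictions; two
  of the 180 published per-estimate error cells differ from the recomputed
  value by exactly one unit in the last printed digit (the published
  errors were evidently computed before rounding). The integrity check
  accounts for this explicitly.
* OKS σ values for fish keypoints are a package default, not a community
  standard; reported OKS-based mAPs are only comparable under identical σ.
* The random-subspace step with two features provides limited
  decorrelation; the forest's advantage over simpler regressors is real
  but modest on smooth allometric data.
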