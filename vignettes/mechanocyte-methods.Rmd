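---
title: "Methods: models, parameters and numerical choices in mechanocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in mechanocyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanocyte)
```

`mechanocyte` analyses combined cell-biomechanics experiments: AFM force
maps, quantitative phase images, fluorescence morphometrics, and
colony / impedance / migration assays. This vignette is the package's own
account of the underlying models, the parameters that matter, and the
numerical decisions taken where the methodology left room.

## 1. The Hertz–Sneddon force-curve model

### Model and assumptions

A force–distance curve records cantilever force `F` (nN) against piezo
position `z` (μm, increasing toward the sample). Below the contact point
`z0` the force is a constant instrumental baseline; above it, contact
mechanics for an elastic, isotropic, semi-infinite sample gives

* cone: `F = (2/π)·E/(1−ν²)·tanθ·δ²`
* four-sided pyramid: `F = 0.7453·E/(1−ν²)·tanθ·δ²`
* sphere: `F = (4/3)·E/(1−ν²)·√R·δ^{3/2}`

with indentation `δ = (z − z0) − F/k`: the piezo travel past contact minus
the cantilever's own bending `F/k`. The model assumes small strains, no
adhesion, and a sample much thicker than the indentation — reasonable for
~1 nN setpoints on cells several μm tall, questionable at cell margins
(see Limitations).

`simulate_force_curve()` is the exact forward model: it solves
`F = baseline + A(E)·δ(F)^m` self-consistently per sample (closed-form
quadratic root for `m = 2`, damped Newton for `m = 3/2`), truncates the
ramp at the first sample reaching the setpoint, and adds Gaussian force
noise last. `fit_hertz()` inverts it by joint nonlinear least squares over
`(E, z0, baseline)` on the whole extend segment (Levenberg–Marquardt via
`minpack.lm`), with `E` parameterised on the log scale so the modulus
stays positive. Inside the fit, the bending correction uses the *measured*
force, the standard practice that makes the residual linear in the
remaining parameters and is exact on noiseless data.

### Parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| tip geometry | — | pyramid | silicon tips on soft nitride levers are four-sided pyramids; cone/sphere selectable |
| half-angle θ | deg | 35 | typical face angle of such probes; the instrument metadata rarely states the indenter model |
| Poisson ν | — | 0.5 | incompressible-cell convention |
| spring constant k | N/m | 0.011 | nominal stiffness of the soft levers used for live cells |
| setpoint | nN | 1 | gentle live-cell mapping force |
| ramp, speed, rate | μm, μm/s, Hz | 15, 30, 2048 | standard mapping protocol; the ramp step `dz = speed/rate ≈ 14.6 nm` follows from them |
| convergence | — | 1e-8 rel., ≤200 iter. | cheap and robust for a 3-parameter fit |

The contact point is initialised by `estimate_contact_point()`: a
ratio-of-variance scan over sliding splits of the extend segment, refined
by a local piecewise flat-plus-quadratic least-squares scan (median error
< 0.1 μm at 0.02 nN noise). It only seeds the joint fit — heuristic
contact points are never reported as results. A curve whose force range
stays below three baseline MADs raises a no-contact error; the fit
propagates it, and non-convergence is flagged (`converged = FALSE`),
never returned as a silent modulus.

## 2. Force maps, setpoint height and segmentation

`build_stiffness_map()` fits every pixel of a force map and records the
**setpoint height** as the piezo z of the last extend sample — the
position at which the setpoint force was reached. Tall cells make contact
earlier, so their setpoint z is *smaller*; `map_topography()` flips this
into a topography with elevated cells for segmentation. Note that the
setpoint-height topography is the true surface minus the indentation
depth, so soft cells appear slightly flatter than they are — a property of
the observable itself, not of the implementation.

`segment_height_map()` smooths (Gaussian, σ = 1 px), estimates the
substrate as a robust plane (least squares on the lowest-decile pixels —
substrate tilt is common in AFM maps), and thresholds at
`max(3 × background MAD, 0.5 μm)` above the plane; the absolute 0.5 μm
floor stops near-noise-free synthetic maps from classifying μm-scale
bump tails as cells. Watershed runs on the foreground relief with a
0.5 μm summit-prominence tolerance (h-maxima-style seeding: below typical
cell height, above map noise). Manual corrections are a replayable edit
script — `merge` / `split` (nearest-seed partition) / `delete` — never
destructive pixel painting, so a corrected segmentation can be reproduced
exactly. Per-cell extraction averages only valid (converged) pixels;
whole-footprint averages are used since a central-region alternative is
equally defensible but less reproducible.

## 3. Quantitative phase and dry mass

Dry-mass density follows `m = φ·λ/(2πα)` (pg/μm²) with defaults
`λ = 0.65 μm` and `α = 0.18 μm³/pg`, the coherence-controlled holographic
configuration and the usual protein refraction increment. The conversion
is strictly linear and never clipped: negative densities (noise) are kept
and flagged, so mass sums stay unbiased; only morphology ignores them.
The holographic background offset is removed beforehand
(`remove_phase_background()`: median phase of non-cell pixels, Otsu-based
if no mask is given).

`segment_qpi()` thresholds at plane + 4 image-wide MADs (the MAD is
robust to the minority of cell pixels), watersheds, and then merges
adjacent basins while the saddle density between them exceeds
`merge_fraction = 0.7` of the lower peak — the package's concretisation
of "watershed with region merging"; 0.7 absorbs shallow internal maxima
(saddle ≥ 0.9 × peaks) with a comfortable margin while keeping distinct
touching cells apart. Mass is conserved by construction: total image mass
= labelled + background mass for any parameters.

Circularity is `4πA/P²` with a **Crofton perimeter** (boundary-intercept
counts along 0°, 45°, 90°, 135°): naive pixel-edge counting overestimates
a disk's perimeter by 4/π and would bias its circularity to ≈ 0.62,
whereas the Crofton estimate is asymptotically exact for smooth convex
shapes (rasterised disks score within 0.02 of 1). Both total mass (pg)
and mean density (pg/μm²) are reported per cell, since either aggregation
is legitimate depending on the question.

## 4. Fluorescence morphometrics

The periphery band is the cell mask minus its erosion by a disc of the
band width (default 4 μm); if erosion empties the mask the whole cell is
the band. Band and interior partition the mask exactly. Intensity
statistics are plain sums and medians over regions (even counts average
the central pair). Shape follows common image-analysis conventions:
max feret = maximal caliper (computed on the convex hull), roundness =
`4A/(π·feret²)`, aspect ratio from the inertia-equivalent ellipse — the
definitions are stated because the names alone are ambiguous across
software.

Fibre orientation dispersion is the circular standard deviation
`√(−2 ln R̄)` of the feret angles. The default `raw` mode applies the
formula to the angles as given (period 360°), matching the common direct
use of a circular-std routine on feret angles; the `axial` mode doubles
the angles and halves the result, the statistically correct treatment for
orientations with period 180°, where 10° and 170° are near-parallel
fibres. Both are exposed because published pipelines rarely state which
was used; axial dispersion is what decreases monotonically with the von
Mises concentration of a fibre population.

## 5. Assay quantification

**Colony plates.** Each photograph is registered to the reference by an
exhaustive rotation scan (±10°, coarse 0.5° then refined to 0.1°) with
FFT cross-correlation for the translation at each angle; a correlation
peak below 0.2 raises a registration failure. Colonies are segmented in
CIE Lab (sRGB input, D65 white point) as pixels with `b < −32`; that
fixed threshold is the b value of a half-coverage blend on the package's
synthetic plates, so a pixel counts as colony when it is majority-stained.
The b channel was chosen over a composite "blueness" score because
trypan-blue staining moves pixels almost purely along the blue–yellow
axis. Override the threshold for a different stain or camera.

**Impedance (RTCA).** `CI(t) = (Z(t) − Z_blank(t)) / Z_nominal`;
`normalize_ci()` divides by the CI at the treatment time (linear
interpolation off-grid — at 15-minute sampling the choice is numerically
minor), making the value there exactly 1. The normalised CI of a
Matrigel-coated well is the relative invasiveness rate.

**Migration.** Per-cell speed is path length over elapsed time. The rose
diagram uses 12 bins of 30° with the first bin centred on +x, weighted by
step speed so fast steps dominate (a speed rose; a count-weighted rose is
one argument away via the weights). The summary vector is
`Σ displacements / Σ path lengths` pooled over all cells — magnitude 1
for straight common motion, 0 for balanced motion, ≤ 1 always by the
triangle inequality; a per-cell-averaged variant is available
(`summary_mode = "per_cell"`). Wound-healing open-area fractions are
accepted as imported percentages only and aggregated to per-well closures;
the upstream image analysis belongs to the dedicated wound software.

## 6. Statistics dispatch

Each group is checked with Shapiro–Wilk at α = 0.05; if all groups pass,
ANOVA is used (repeated-measures `value ~ group + Error(pair)` when a
pairing key exists — the natural reading of a "paired" multi-group
design — one-way otherwise), else Kruskal–Wallis. Constant groups force
the nonparametric branch with a warning. The branch and the per-group
normality p-values are returned, making the decision auditable and
reproducible. Note the gate's arithmetic: with three groups the
all-normal probability under a true normal null is 0.95³ ≈ 0.86, so about
14% of perfectly normal datasets legitimately route to Kruskal–Wallis;
the dispatched procedure still holds its ~5% size because both branches
do. Correlations dispatch the same way (Pearson if both variables pass,
Spearman otherwise). No multiple-testing correction is applied by
default, mirroring the common single-comparison reporting; Holm can be
applied by the caller. Comparative Ct is
`2^(−ΔΔCt)` with `ΔCt = Ct_target − Ct_reference` and the calibrator at
expression 1; it is invariant to shifting all reference-gene Ct values.

## 7. Synthetic data: what it emulates, and what it does not

Every generator is deterministic under a fixed master seed, drawing from
a named substream (`seed`-derived, one per modality) so adding one
generator to a workflow never perturbs another's draws.

* `gen_force_map()` — Gaussian-bump cells (radius 12 μm, height 3 μm) on
  a 10 kPa substrate, per-pixel curves through the exact forward model
  with 0.02 nN noise, default 64 × 64 grid; cell truth masks are the
  regions more than 0.5 μm proud of the substrate.
* `gen_phase_image()` — flat-core/cosine-rim mass profiles normalised so
  each cell's deposited mass is exact, inverted through the dry-mass law,
  plus 0.15 rad background offset and 0.01 rad noise.
* `gen_fiber_image()` — line segments with Gaussian cross-section and von
  Mises orientations (Best–Fisher sampler); the truth records the drawn
  angles and their circular dispersion.
* `gen_colony_image()` — white plate, non-overlapping anti-aliased blue
  disks until the target ROI coverage; truth is the exact rasterised
  fraction.
* `gen_tracks()` — persistent random walks with a common drift blended in
  by `bias` (0 = unbiased, 1 = straight); constant step length makes the
  realised speed exact by construction.
* `gen_impedance()` — logistic cell-index growth on the 15-minute /
  150-hour grid (601 samples), a post-treatment rate multiplier, noise
  added in CI space and inverted through the CI formula so
  `cell_index()` recovers the stored truth exactly.

These fixtures validate the *computational* chain: geometry, estimators,
bookkeeping, statistics. They do not emulate viscoelastic lag, adhesion,
finite cell thickness, optical halo or phase unwrapping artefacts,
uneven illumination, or camera noise spectra — passing tests therefore
demonstrate correctness of the analysis, not robustness to every
instrumental artefact of real data.

## 8. Numerical choices and degenerate inputs

* Quadratic contact solved with the cancellation-stable root
  (`2c / (−b + √D)`), exact down to the rigid-lever limit `k → ∞`.
* Fits report `converged`, iteration count and RSS; downstream maps flag
  and exclude failed pixels, warning when more than half a map fails.
* Empty foreground segments to an empty mask (0 cells), not an error;
  zero-area labels are skipped with a message.
* Region merging recomputes interface saddles after every merge
  (images are small; clarity beats asymptotics).
* Ties in the nearest-seed split go to the first seed; labels are always
  renumbered consecutively.
* Angle dispersion clamps `R̄ ≤ 1` before the log to absorb rounding.

Problem sizes in the shipped tests and acceptance script — 24 × 24 force
maps, 160 × 160 phase images, 240 × 240 plates, 100 tracks, 2000
dispatch replicates — were chosen as the smallest instances whose
sampling error sits comfortably below the tolerances being asserted;
all scale linearly to instrument-sized data (64 × 64 maps, megapixel
images).

## 9. Known limitations

* The Hertz family here is purely elastic; at 30 μm/s approach speeds
  real cells show viscoelastic stiffening that the model folds into `E`.
* Setpoint-height topography under-reports soft-cell height by the
  indentation depth (§2).
* Thin cell margins violate the half-space assumption; per-cell means
  over the whole footprint inherit that bias.
* Registration is rigid (translation + rotation) only; plates imaged at
  different magnifications need external rescaling.
* The colony threshold is calibrated for trypan-blue-on-white imagery.
* `raw`-mode angle dispersion depends on the angle convention of the
  upstream feret computation; prefer `axial` for new analyses.
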