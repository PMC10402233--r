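---
title: "Methods: phosphene shape, axonal geometry, and the summation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphene shape, axonal geometry, and the summation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phosphenes)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the spirit of a methods section: what is computed,
under which assumptions, and where a genuinely open design choice was
settled.

## 1. From drawings to shape descriptors

A drawing is a binary raster mask; throughout the package **x is the column
index and y the row index, both 0-based**. Image moments are sensitive to
this convention, so it is fixed once here: the raw moments of a mask are
\(M_{ij} = \sum_x \sum_y x^i y^j I(x,y)\), giving area \(A = M_{00}\),
centroid \((M_{10}/M_{00},\, M_{01}/M_{00})\), and central second moments
\(\mu'_{20}, \mu'_{11}, \mu'_{02}\). Major and minor axis lengths are
\(4\sqrt{\lambda_{1,2}}\) for the eigenvalues of the 2×2 central-moment
matrix — for a filled ellipse this recovers exactly its axis diameters,
which is why the factor is 4 and not 2.

**Region connectivity is 8-connected.** Hand-drawn touchscreen strokes
produce diagonal pixel adjacency, and treating diagonally touching strokes
as separate phosphenes would inflate counts. Labeling is implemented in
C++ with deterministic raster-scan label order and is cross-checked in the
tests against a pure-R breadth-first-search oracle.

**Perimeter** uses the weighted border-pixel-count algorithm: border pixels
(mask minus its 4-connected erosion) are classified by their 3×3 border
pattern and weighted 1 (straight), \(\sqrt 2\) (diagonal) or
\((1+\sqrt 2)/2\) (corner), approximating the length of the polyline
through connected border-pixel centers. The weights are a declared constant
validated against frozen reference values of the original algorithm and an
independent per-pixel recomputation. A single isolated pixel has perimeter
0 (a polyline through one point has no length), and the minor axis of
collinear pixels is 0.

**Drawing validation.** Valid drawings must have closed contours. The
automated stand-in for manual contour inspection is a morphological closing
(disc-shaped structuring element, default radius 1 px — one touchscreen
"pen slip") followed by hole filling; the pixels added by each step are
logged per drawing in the `validationLog` attribute so the cleaning is
auditable. The mask is padded before closing so the operation cannot
interact with the canvas border. Grayscale input must be binarized
explicitly (`binarizeMask()`, cut point 0.5).

**Small-spec filter.** Within each trial set (all drawings of one
electrode × stimulus condition), a region smaller than 10 px is discarded
as an additional phosphene *unless* small regions appear in at least 50 %
of that condition's drawings, in which case they are treated as real,
reproducible percepts. The filter operates on the validated
(hole-filled) masks: whether the 10 px rule should see pre- or post-fill
areas is not decidable from first principles, and post-fill was chosen
because the fill stage is part of what makes a drawing a percept region at
all; `fillHoles = FALSE` exposes the alternative. Per-drawing descriptors
are the sums over surviving regions, which makes multi-phosphene drawings
comparable to single-phosphene ones; the filter is idempotent.

**Mean images** average a condition's drawings after removing translation:
whole-drawing alignment shifts each drawing so its center of mass sits at
the trial-averaged center of mass (integer shifts, so binary masks stay
binary); the per-phosphene mode aligns each connected region separately,
with regions matched across trials by centroid rank order — a deliberate
simplification that is exact when phosphene layouts are stable across
trials and approximate otherwise.

## 2. The axon map and axonal distances

Retinal coordinates are canonical right-eye: fovea at the origin, optic
disc toward +x (default center (4600, 260) µm), horizontal raphe along the
temporal −x axis, superior retina y > 0; left-eye placements are mirrored
at ingest. The default retinal magnification is 288 µm/°, under which the
200 µm electrode subtends 0.7° to one decimal.

Nerve-fiber bundles are modeled as a spiral family around the optic-disc
center, indexed by the disc entry angle \(\phi_0\) (degrees from the
temporal horizontal, positive superior):
\[
\phi(r) = \phi_0 + b\,(r - r_0)^c, \qquad r_0 = 4^\circ,
\]
with \(b\) and \(c\) given by tanh fits with distinct parameter regimes for
the superior and inferior hemiretina (defaults
\(b = -\exp(-1.9 + 3.9\tanh(-(\phi_0-121)/14))\),
\(c = 1.9 + 1.4\tanh((\phi_0-121)/14)\) superior;
\(b = \exp(0.5 + 1.5\tanh(-(|\phi_0|-90)/25))\),
\(c = 1.0 + 0.5\tanh((|\phi_0|-90)/25)\) inferior). These constants live in
the `AxonMap` object and are configurable; the tests exercise the
family's structural properties rather than any single constant: both
hemifields bend toward the raphe, trajectories never cross the horizontal
meridian on the temporal side (near-raphe trajectories are clamped exactly
at y = 0, since the raw power law overshoots there — a known artifact of
this parameterization), hemifields mirror exactly when given mirrored
parameters, and bundles through on-raphe points hug the horizontal axis
within 5 % of their eccentricity over their raphe-adjacent extent.
Polylines are discretized at a 10 µm arc-length step (halving the step
changes distance queries by < 1 %), ordered from the peripheral end to a
terminal vertex at the disc center.

`axonBundle()` finds the trajectory passing closest to a point by scanning
a dense fan of seed angles (default 181 per hemifield) and refining the
entry angle by golden-section search; results are memoized per query
point.

**Pair decomposition.** For two electrodes, the more nasal one is the one
with larger x (ties broken by |y|, the electrode farther from the
horizontal counting as temporal — an arbitrary but deterministic rule).
The *reference bundle* is the bundle through the **temporal** electrode;
the **between-axon** distance is the minimum distance from the nasal
electrode's center to that bundle, and the **along-axon** distance is the
arc length along it from the temporal electrode's foot point to the foot
point of the between-axon segment. Published verbal definitions of the
along-axon component are ambiguous about whose bundle serves as the
reference; the geometric construction adopted here (single reference
bundle through the temporal electrode, as in the diagrammatic definition)
is the one that remains well defined for pairs straddling the raphe.
Between-axon can never exceed the Euclidean separation because the
reference bundle passes through the temporal electrode. Both quantities
are validated against a brute-force oracle on 1 µm-resampled polylines.

Electrode–retina distances enter only as given numbers; the package
provides the OCT shadow arithmetic
(`distance_px × 200 µm / shadow_width_px`) but no image analysis.

## 3. Preprocessing conventions

The pipeline order is: standard-pulse normalization → trial averaging →
power transform → outlier screening → predictor standardization
(`prepareDesign()`).

- **Standard-pulse normalization**: each descriptor is divided by the
  participant's mean descriptor over all of their single-electrode
  drawings at the standard stimulus (2× threshold, 20 Hz), pooled across
  electrodes. This absorbs each participant's drawing bias and scale; by
  construction the normalized standard-pulse mean is exactly 1 per
  participant, which the tests assert. A participant with no standard
  drawings is a hard error naming them.
- **Averaging** collapses repeated trials of the same
  (participant, electrode(s), amplitude, frequency) cell to its mean,
  eliminating repeated measures; the trial count is retained.
- **Power transforms** stabilize residual normality: area^(1/3) (area
  grows quadratically with linear size, and its cube root is closest to
  symmetric in practice), square roots for perimeter and axis lengths.
  Both transforms are strictly monotone, so orderings are preserved.
- **Outlier rule**: a data point is removed when *any* of its four
  transformed descriptors lies more than 2.5 population SDs from its
  participant-group mean. The joint (any-descriptor) rule, rather than
  per-descriptor masks, keeps a single analysis set across descriptor
  tables. The screen applies to single-electrode analyses only — paired
  sets are small enough that a 2.5-SD rule would be dominated by its own
  scale estimate. Zero-variance groups remove nothing.
- **Standardization uses the population SD** (divisor n, the scipy
  convention): {1, 2, 3} maps to {−1.2247, 0, 1.2247}. Predictors are
  z-scored across all participants *after* outlier removal, so removed
  rows do not influence the scaling (the alternative order is available by
  calling `assembleDesignTable()` directly). A predictor that is constant
  (for example electrode–retina distance in a participant whose array is
  fully apposed) is dropped rather than scored; within-participant fits
  must likewise omit predictors constant within that participant, since
  `fitStandardizedOls()` treats a constant column as a rank error.

## 4. The statistical battery

- `fitStandardizedOls()` fits ordinary least squares on z-scored response
  and predictors (so coefficients are standardized betas) and reports
  **partial correlations by residualization**: the correlation between the
  residuals of y and of each predictor after regressing both on the
  remaining predictors. This is equivalent to the t-statistic transform
  \(r = t/\sqrt{t^2 + df}\); residualization is implemented as the primary
  route because it makes the convention explicit. Betas and partial r
  always share sign, and the fit is invariant to affine rescaling of raw
  predictors.
- `fitSummationRegression()` is the no-intercept simple regression
  \(\beta = \sum xy / \sum x^2\) of a paired-electrode descriptor on the
  sum of the two single-electrode descriptors; no intercept, because a
  zero predicted percept must map to a zero paired percept. A slope in
  (0.5, 1) is flagged: paired percepts larger than the average but smaller
  than the sum of their singles.
- `fitMixedModel()` adds a participant random intercept (random slopes
  are deliberately out of scope: with three groups they are not
  estimable). Predictors are z-scored; the response keeps its scale so
  per-group shifts are absorbed by the intercepts and slopes are
  shift-invariant. Estimates are REML with Satterthwaite p-values
  (lmerTest); **AIC/BIC come from the maximum-likelihood refit**, because
  REML likelihoods are not comparable across fixed-effect structures.
  Singular fits (zero between-group variance) are legitimate and reduce
  to pooled least squares; hard optimizer failures are errors.
- `compareModels()` applies the conventional evidence bands: Δ < 2 "both
  supported"; 2 ≤ ΔAIC < 7 (2 ≤ ΔBIC < 6) "some evidence"; ΔAIC ≥ 7
  (ΔBIC ≥ 6) "strong evidence" against the higher-scoring model. Both fits
  must share the response (equal n is enforced; AIC constants cancel in
  the difference because both models carry the same Gaussian likelihood
  form, including the estimated variance parameter).
- `welchTFromSummary()` computes \(t = (m_1 - m_2)/\sqrt{sem_1^2 +
  sem_2^2}\) from printed summaries. Published tables sometimes print such
  t values with a shared nominal df (e.g. 29 for two groups of 30) rather
  than the Welch–Satterthwaite df; only the t value itself is reproduced
  here, and no df is reported.
- Bonferroni adjustment is min(1, p·m), with the family size m explicit —
  in descriptor tables the natural family is predictors × descriptors
  (e.g. 12 for 3 predictors and 4 descriptors).
- Two-sided p-values throughout; `qqNormality()` summarizes a Q-Q plot as
  the correlation between sorted residuals and normal quantiles.

## 5. The synthetic drawing generator

The generator exists so that every stage of the pipeline — and every
recovery claim — can be exercised against known ground truth. It renders
the axon-map intensity model: for electrode e with bundle a(s)
(arc length s from the electrode's foot point),
\[
I(p) = \max_s \exp\!\big(-\|p - a(s)\|^2 / 2\rho_{\mathrm{eff}}^2\big)\,
       \exp\!\big(-s^2 / 2\lambda_{\mathrm{eff}}^2\big),
\]
binarized at threshold θ = 0.5. The maximum-over-bundle-points form (rather
than a separable perpendicular × along product) is used because it has the
correct limits: λ → 0 reduces to an isotropic current-spread blob, large λ
gives percepts elongated along the bundle. Stimulus and anatomy enter as
\(\rho_{\mathrm{eff}} = \rho_0 A^a\) and \(\lambda_{\mathrm{eff}} =
\lambda_0 (1 + f \log(F/20)) (1 + c\,\mathrm{EFD_{mm}})\): amplitude grows
percepts, frequency and eccentricity elongate them, matching the
qualitative single-electrode phenomenology the analysis is designed to
detect.

**Paired stimulation** takes the pixelwise maximum of the two intensity
fields and binarizes at the *gain-elevated* threshold \(\tau = \theta^g\).
For Gaussian profiles the area of the superlevel set is proportional to
\(\ln(1/\tau)\) in both the blob and the elongated regime, so each
non-merging component's area is exactly g times its single-electrode
counterpart in the continuous limit — the configured gain g (default 0.7)
*is* the ground-truth summation slope, and pixelization is the only source
of bias (measured < 1 % at the default rasters). The noiseless connected-
component count is the ground-truth phosphene number: electrodes on nearby
bundles merge into one component however far apart they are on the retina,
which is precisely the between-axon mechanism the model comparison should
detect.

**Noise model**: a per-trial log-normal size bias (SD 0.1 on the log
scale) multiplying both spread scales, and integer centroid jitter (SD
4 px) of the drawn mask — a minimal emulation of drawing bias and
variance. It does not model stroke width, tremor, memory decay between
stimulus and drawing, partial drawings, or fading percepts; passing
recovery tests therefore show the pipeline is correct and well-calibrated
under the stated generative model, not that real drawings satisfy it.

**Default conditions.** Three participants with distinct phenotypes:
ρ0 = (150, 70, 110) µm, λ0 = (400, 900, 500) µm (one "line-drawer" with
large λ/ρ), amplitude exponents (0.5, 0.12, 0.8) (one participant nearly
amplitude-insensitive), frequency coefficients (0.08, 0.12, 0.5) (one
strongly frequency-sensitive), eccentricity coefficient 0.25 per mm, gain
0.7, 5 trials per stimulus cell, amplitudes 1.25–6× threshold, frequencies
6–120 Hz with the 2×/20 Hz standard cell always present. Implant
placements (rotations −20°, 5°, 15°; centers chosen once) reproduce mean
electrode–fovea distances of ≈ 2561, 2136 and 2169 µm, the reported
per-participant eccentricity regime. The default raster is a 1024 × 768 px
touchscreen at 25 px/° (a ~76 cm viewing distance); electrode–retina
distances are carried as metadata only (nonzero for one participant) and
have no generative effect, so their null recovery is itself a check.

## 6. Problem sizes and numerical choices in the validation suite

The test and acceptance analyses run on a 400 × 300 px raster at 10 px/°
— the same statistical parameters at a coarser drawing resolution, chosen
so the full battery (moment oracles on 100 random masks, 1 µm
dense-sampling distance oracles on 200 electrode pairs, 100-pair gain
recovery, a ~100-cell single-electrode study, and 20 seeds × 40 pairs of
the phosphene-number comparison) completes in minutes while keeping
phosphene areas in the hundreds of pixels. Bundle polylines are resampled
for rendering at half the smaller Gaussian scale (curvature radii are
millimeters, so chord error is sub-micrometer), and the rendered window is
restricted to 2 SD of the active bundle segment, outside of which
intensity is provably below any threshold ≥ e⁻² ≈ 0.135.

Degenerate inputs are errors, not silent results: empty regions for
descriptors, non-binary masks, constant vectors for z-scores, collinear
or constant predictors, identical electrodes for pair distances, points
inside the optic disc for bundle queries, participants without standard
pulses for normalization.

## 7. Known limitations

- The fiber-bundle constants are a population-average parameterization;
  no subject-specific fundus fitting is provided (placement enters as
  parameters by design).
- Per-phosphene correspondence in mean images is by centroid rank, which
  can mismatch regions when layouts differ strongly across trials.
- The generator's perceptual gain acts through threshold elevation; it
  reproduces descriptor-level summation but is not a biophysical model of
  charge interaction.
- Within-participant regression tables must be assembled by the user per
  participant (dropping predictors constant within that participant);
  the package enforces, but does not automate, that choice.
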