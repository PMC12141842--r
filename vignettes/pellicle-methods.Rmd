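---
title: "Methods: pellicle deformation mapping, tensile mechanics, and morphogenesis kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pellicle deformation mapping, tensile mechanics, and morphogenesis kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pellimetry analyses two kinds of experiments on bacterial pellicles
(biofilms at the air–liquid interface): a uniaxial stretching assay in
which a mature pellicle clamped between two plates is elongated while a
force sensor records the transmitted load and a camera records the surface,
and time-lapse recordings of pellicle morphogenesis in a rectangular dish.
This vignette explains the models and estimators, the tunable parameters
and their defaults, the synthetic-data generator used for testing, and the
numerical choices made where the design was genuinely open.

## The stretching assay and its coordinate system

One plate ("immobile") is attached to a double-cantilever force sensor of
stiffness 19.5 mN/mm; the other ("mobile") is driven by a translation stage
at 160 µm/s over up to 12 mm, with the force sampled every 100 ms
(`pull_protocol()`). Positions along the elongation axis are expressed
relative to the two plates: `x_rel = 0` at the immobile plate, `x_rel = 1`
at the mobile plate, separated by 13–14 mm. Because a tensile force `F`
deflects the cantilever, the "immobile" plate actually moves by
`F / 19.5 mm`; both the deformation mapping (`profile_from_field()`'s
`sensor_correction_mm`) and the mechanics (`pellicle_elongation()`) account
for this.

## Deformation model

A homogeneous elastic sheet stretched uniaxially displaces affinely:
`u_rel = x_rel` (slope 1 through the origin). Composite pellicles instead
follow a continuous piecewise-linear profile. The canonical rough-pellicle
profile (`canonical_rough_nodes()`) has nodes (0, 0), (0.15, 0.33),
(0.70, 0.60), (0.95, 0.60), (1, 1): a *soft* edge region next to the
immobile plate absorbing one third of the elongation, a *central* region
absorbing 27 % (slope 0.27/0.55 ≈ 0.49), a *rigidly translating* region at
constant relative displacement 0.60, and a narrow, quasi-discontinuous
*step* next to the mobile plate taking up the remaining 40 %. These nodes
form the minimal piecewise-linear curve consistent with the region
intervals and fractions of the assay; the profiles themselves are what PIV
measures.

Two consequences used throughout: the elongation fraction of a region is
`u_rel(x_hi) − u_rel(x_lo)` (fractions over a partition of [0, 1] sum
to 1), and a plate travel `d` produces a true elongation `φ·d` of a region
with fraction `φ` — e.g. 3.7 mm of travel elongates the central region
(φ = 0.27) by ≈ 1 mm, and 0.6 mm of travel elongates the narrow step
(φ = 0.40) by 0.24 mm.

## PIV

`compute_field()` slices the image pair into interrogation windows
(default 32 × 32 px) matched inside larger search windows (50 × 50 px,
giving lags of ±9 px) by *normalized* cross-correlation: both windows are
centred and scaled, so scores lie in [−1, 1] and are comparable across
illumination. Displacement is the motion of matter from image A to
image B. Design choices where the method itself leaves freedom:

* **Grid**: anchored so every search window fits in the frame; stride set
  by `overlap_fraction` (default 0.5, i.e. 16 px). For profiles that must
  sample close to a breakpoint (e.g. the soft region ending at
  `x_rel = 0.15`) we use overlap 0.75 (8 px stride).
* **Subpixel peak**: independent per-axis three-point Gaussian fit,
  falling back to a parabolic fit when a neighbour score is non-positive;
  refinement is bounded to ±0.5 px. When the integer peak already scores 1
  (an exact match) no refinement is applied, since any fractional shift
  could only reduce the correlation; this makes zero-displacement and
  integer-translation cases exact rather than subject to the small
  asymmetry bias of three-point estimators.
* **Low-contrast windows** (grey-level s.d. below `min_contrast`, default
  1) are flagged invalid instead of producing spurious peaks; peaks on the
  search border are kept at integer precision and flagged.
* **Validation** (`validate_field()`): a vector is an outlier when it
  deviates from the median of its 3 × 3 neighbourhood by more than
  `median_k` (default 3) times the local median absolute deviation, with a
  0.1 px noise floor. The test median *includes* the centre vector — a
  centre-excluded median systematically leads or lags on displacement
  gradients at the grid border and would flag valid edge vectors — while
  the replacement value is the median of the neighbours excluding the
  centre. `peak_quality` (ratio of first to second correlation peak) is
  reported per vector.

`profile_from_field()` collapses the field to one dimension with the
per-station *median* of valid axial displacements (robust to stray vectors
and meniscus effects at the transverse edges). Only the axial component is
used. The per-point uncertainty is one pixel divided by the applied
elongation in pixels. Displacement gradients steeper than a few px per
window side (the interior of the step region) decorrelate the windows and
are not resolvable — consistent with such regions being reported only as
"stiffer than detectable" in this kind of assay.

## Piecewise fitting

`fit_piecewise()` fits a continuous piecewise-linear model through a hinge
basis `u = c₀ + c₁x + Σᵢ gᵢ(x − bᵢ)₊`, with the interior breakpoints found
by exhaustive search over a 0.01-step grid, minimising the sum of squared
residuals; ties break deterministically to the leftmost breakpoints, and
every segment must contain at least 2 data points. Continuity is enforced
because measured profiles are continuous; free-intercept segments are not
allowed. The end segments are extrapolated to `x_rel = 0` and 1 to form
the fitted nodes. Tests verify that the grid search never loses to a
brute-force search over all data-supported breakpoint combinations, and
that adding segments never increases the residual. The number of segments
is a user parameter (4 for rough-type, 1 for smooth-type profiles); when
choosing automatically, we recommend accepting an extra segment only when
it drops the residual sum of squares by more than 25 %.

`classify_regions()` labels fitted segments: slope ≤ 0.1 ⇒ rigid
translation; width ≤ 0.1 with slope > 1 ⇒ step; a first segment adjoining
`x_rel = 0` with slope > 1 ⇒ soft; otherwise central. Both thresholds are
tunable.

## Mechanics

The raw sensor channel is either deflection (µm) or pre-converted force
(mN), declared in the trace header; `deflection_to_force()` applies
`F = 19.5 mN/mm × deflection`. The analysis chain is:

1. **Zero calibration** (`zero_calibrate()`): after failure the pellicle
   transmits no force, so the mean signal over the last 2 s of the record
   measures the sensor's zero and is subtracted; the operation is exactly
   idempotent. A window reaching into pre-failure samples is rejected.
2. **Elongation correction** (`pellicle_elongation()`):
   `e = d − F/19.5` (the correction is ≈ 0.08 mm at 1.5 mN, small but
   systematic).
3. **Failure detection** (`detect_failure()`): failure is an abrupt,
   *permanent* loss of force — the first sample below `drop_fraction`
   (default 0.5) of the running maximum over the previous 5 samples, that
   stays below for 3 consecutive samples (`persistence`), with the
   pre-drop level at least `min_force` (0.5 mN). The persistence
   requirement exists because near the `min_force` level a single noise
   dip can otherwise satisfy the drop criterion and truncate the elastic
   fit; a broken pellicle never recovers its load, a noise dip does.
4. **Elastic fit** (`fit_elastic()`): least squares of force on elongation
   over 5–90 % of the failure elongation, excluding seating transients at
   the start and crack initiation just before failure. The slope in mN/mm
   is the stiffness in N/m (numerically identical); the intercept is the
   force at zero elongation, negative when a residual compressive force
   from growth under confinement is present.
5. **True-strain correction** (`correct_true_strain()`): for composite
   pellicles the reported axis is `φ·d` with `φ` the central-region
   elongation fraction (0.27 for the canonical rough profile), so the
   fitted slope is the stiffness of the deforming region itself.
6. **Rescaling** (`rescale_stiffness()`): a uniform strip's stiffness
   scales inversely with length (`k·L` conserved), so a segment occupying
   a fraction `φ_L` of the specimen corresponds to a full-length stiffness
   `k·φ_L`. Note that for a central segment with `φ_L = 0.55` and
   k = 5.1 N/m this rule gives 2.805 N/m, whereas a value of 2.5 N/m is
   sometimes quoted for this configuration; the package implements the
   scaling law and does not attempt to reconcile the rounded figure.

Replicate summaries (`summarize_mechanics()`) are unweighted means ± s.d.
over pellicles, with failure strain as `100 × e_fail / gap`.

## Kinetics

`gray_profile()` samples grey values with bilinear interpolation along a
probe line; `build_kymograph()` stacks one profile per frame (row *t*
equals the profile of frame *t* exactly). `track_front()` takes the front
as the outermost position where the profile crosses a grey threshold
(linear interpolation between samples), skips rows without a crossing
(erroring if more than half are skipped), and reports the least-squares
slope of position on time as the front speed with its R².

`wrinkle_wavelength()` detrends the profile by subtracting a moving-average
baseline (window = twice the upper band limit), then takes the dominant
wavelength as the **first** autocorrelation peak inside the wavelength band
exceeding 0.2, refined by a parabolic fit; the periodogram maximum inside
the band is reported as a consistency check. Autocorrelation is primary
because wrinkle profiles need not be sinusoidal; the first-peak rule picks
the fundamental spacing rather than a slowly varying envelope. Profiles
with no qualifying peak are classified aperiodic (white noise at
n ≈ 800 samples stays well below the 0.2 threshold).

`expansion_rate()` converts colony diameters to rates. Published
colonization rates are radius-like, so the default is
`(diameter − baseline) / (2·time)`; the diameter convention is available
and the convention used is recorded on the result, because diameter tables
alone do not identify the convention behind a quoted rate.

## The synthetic-data generator

The generator produces the three input types with known ground truth:

* **Speckle images**: Gaussian-profile grains (Poisson count at
  `grain_density` per 1000 px², uniform centres) on a flat background plus
  Gaussian noise, clipped to [0, 255]. This emulates the optically visible
  inhomogeneities of a real pellicle that PIV uses as tracers, with a
  controllable correlation length (grain radius, default 2 px). Real
  pellicle texture statistics are not documented; these parameters are
  stated, not claimed realistic.
* **Warped pairs**: backward warping (output samples the source at
  `x − u(x)`, bilinear, clamped at edges) by any profile; backward mapping
  avoids the holes of forward splatting. Because the warp prescribes
  `u` at output coordinates, PIV recovers `u/(1 − u′)` at the station —
  a ≤ 3 % effect at the gradients used here, well inside the tolerances.
* **Force traces**: `F = F₀ + k·φ·d` up to the failure elongation, then a
  single-sample drop to the post-failure level (failure is "sudden";
  sharpness also makes detection tests unambiguous), plus Gaussian noise
  and an optional constant sensor offset that the zero calibration must
  remove. 1 N/m ≡ 1 mN/mm is used throughout.
* **Time-lapse stacks**: a bright pellicle region whose boundary advances
  at `front_speed` after an onset, a sinusoidal grey modulation of fixed
  wavelength inside the pellicle after a wrinkle onset, and seeded noise.
  The dish defaults to 62 × 46 mm at 0.05 mm/px.

Every generator is a pure function of (spec, seed): identical inputs give
bit-identical outputs, and the caller's RNG state is untouched. What the
generator does *not* emulate: photorealistic texture, bacterial growth and
matrix production, buckling physics (wrinkles are imposed, not emergent),
3-D geometry, menisci, or illumination drift. Passing tests therefore
demonstrate estimator correctness on data satisfying the stated models,
not robustness to every artefact of real recordings.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to exercise the estimators while
remaining desk-scale: PIV on an 800 × 400 px pair (12 px total elongation,
~2 000 vectors at 8 px stride); piecewise fits on 31–51-point profiles
with the 0.01 breakpoint grid; force traces at the full protocol rate
(751 samples over 75 s); kymographs over the 62 mm dish width with a
reduced 10 mm transverse extent, since a line probe does not use the
transverse direction; wavelength detection on 40 mm profiles
(801 samples). Degenerate inputs error early with typed input errors:
non-positive dimensions, unresolvable wavelengths (< 2 px), probes outside
the image, degenerate abscissae, calibration windows overlapping
pre-failure data.

## Known limitations

* Single-pass PIV without iterative window deformation: displacement
  gradients steeper than a few px per window (the step region's interior)
  decorrelate and are left to the fitted model's extrapolation.
* The piecewise fit's exhaustive search is O(grid^k) in the number of
  interior breakpoints; it is intended for k ≤ 3–4.
* Wrinkle detection assumes an approximately stationary spacing inside the
  band; strongly hierarchical or drifting patterns report only the
  dominant scale.
* Out-of-plane (vertical) displacements are neglected throughout the
  deformation analysis; wrinkle flattening during stretching is not
  modelled.
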