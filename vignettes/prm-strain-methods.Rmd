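---
title: "Fiber-direction strain imaging of the puborectal muscle: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber-direction strain imaging of the puborectal muscle: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prmstrain)
```

## The measurement problem

The puborectal muscle (PRM) is a sling: its fibers leave the pubic
symphysis on one side, curve around the anorectal junction, and return to
the bone on the other side. Conventional 3D transperineal ultrasound shows
its geometry but not its function. Strain imaging fills that gap: if the
granular speckle pattern of the ultrasound volume can be tracked from rest
to maximum voluntary contraction, the spatial gradient of the tissue
displacement *along the fiber direction* is the local relative shortening
(negative strain) or elongation (positive strain) of the muscle.

The clinically interesting signal is an asymmetry. An intact PRM is
anchored to bone at both ends: during contraction the sling's mid region
shortens and both ends, still tied to the bone, are stretched (positive
strain). After a unilateral avulsion one end has lost its bony anchor; it
contracts together with the sling instead of elongating. Summarizing
strain medians in three regions (right end, mid, left end) and forming the
normalized strain ratio

$$
\mathrm{ratio} \;=\;
\frac{\left| \varepsilon_\mathrm{right} - \varepsilon_\mathrm{left} \right|}
     {\left| \varepsilon_\mathrm{mid} -
       (\varepsilon_\mathrm{right} + \varepsilon_\mathrm{left})/2 \right|}
$$

turns this asymmetry into a single dimensionless number: symmetric
(intact) ends give a small numerator, hence ratios below 1; an avulsed end
drives the numerator past the mid-versus-ends contrast, giving ratios
above 1. The ratio is invariant to adding a constant to all three medians,
to flipping all signs, to rescaling, and to swapping the two ends — so it
is insensitive to how strongly a particular subject contracts, which
varies widely.

## Pipeline

`run_subject()` chains six stages; each is exported on its own.

1. **Speckle tracking** (`estimate_displacement`): block matching by
   normalized cross-correlation (NCC). For each voxel of the region of
   interest, a block (default $5^3$ voxels) is compared against the next
   frame over a search window (default $\pm 5$ voxels); the displacement
   with the highest correlation wins, ties going to the smaller shift, and
   a three-point Gaussian fit along each axis refines the peak to subvoxel
   precision. Summed-volume tables make the block statistics $O(1)$ per
   search offset, so a full frame pair tracks in seconds on one CPU.
2. **Quality filtering and regularization** (`quality_filter`,
   `smooth_field`): vectors whose peak correlation falls below
   `min_quality` are replaced by the component-wise median of their valid
   neighbours and flagged as interpolated; the field is then smoothed by a
   NA-aware Gaussian (`smooth_sigma`, default 1.2 voxels).
3. **Motion-compensated refinement** (`refine_displacement`): the moving
   volume is warped back by the current field and the residual is
   re-estimated with a small search. Two passes (the default) remove most
   of the deformation-induced skew of the correlation peak, which would
   otherwise accumulate coherently over the frame sequence. The
   regularization strength and pass count were calibrated once against
   the phantom's analytic ground truth over a grid of seeds and
   conditions; both matter most near the freely sliding end of an avulsed
   muscle, where single-pass estimates keep a realization-dependent bias.
4. **Propagation and accumulation** (`propagate_sequence`, `accumulate`):
   displacements are composed Lagrangianly — a material point at rest
   position $x$ with accumulated motion $u_t(x)$ receives the next
   increment interpolated at $x + u_t(x)$. The segmentation is carried to
   each frame by splatting the rest-mask material points through the
   accumulated field (plus a one-voxel closing). An Eulerian per-voxel
   summation mode exists for comparison; it is only valid while total
   motion stays below a voxel.
5. **Centerline and projection** (`extract_centerline`, `build_arc_map`,
   `project_displacements`): the muscle mask is reduced to a medial path
   (below), fitted per coordinate by a least-squares polynomial (default
   degree 5) over normalized chord length, resampled densely, and each
   mask voxel is assigned the arc coordinate and unit tangent of its
   nearest centerline sample. The tangent field is the working proxy for
   the local muscle-fiber direction.
6. **Strain and regional summary** (`lsq_strain`, `compute_strain_series`,
   `partition_regions`, `region_medians`, `normalized_strain_ratio`): per
   voxel, the $2 \times 2 \times 2$ window's displacements are regressed
   against arc coordinate; the slope, in percent, is the fiber-direction
   strain. Regional medians are taken at the maximum-contraction frame
   (the frame whose mid-region median is most negative, ties to the
   earliest; `select_max_contraction`).

## Design choices worth knowing about

**Window tangent versus per-voxel tangent.** `lsq_strain` implements the
textbook least-squares strain estimator on scalar projections: each
voxel's displacement is projected on its own nearest tangent and the
window slope of projection versus arc coordinate is the strain. On a
curved centerline this form has a blind spot: a *rigid translation* $u$
produces a projection $u \cdot \hat t(s)$ that varies along the curve, so
it registers an apparent strain $\kappa\, (u \cdot \hat n)$ — at this
muscle's curvature ($\kappa \approx 0.05\,\mathrm{mm}^{-1}$), several
percent strain per millimetre of translation, which would swamp the
signal whenever the whole pelvic floor shifts. The pipeline therefore
projects all window members on the *window center's* tangent
(`lsq_strain_vec`): for a constant displacement the projections are then
constant and the slope is exactly zero, while for tangential contraction
the two forms agree to second order in the window size. The scalar form
remains exported and is what the per-neighbourhood regression tests
verify against closed-form normal equations.

**Terminal versus incremental projection.** The default (`mode =
"terminal"`) projects each frame's accumulated displacement onto the
rest-frame centerline geometry. The alternative (`mode = "incremental"`)
recomputes the centerline on every propagated mask and accumulates
per-frame strain increments evaluated with the current tangents — an
angle correction that matters when the muscle rotates substantially
during contraction. On the phantom, whose peak rotation is about
9 degrees, the correction is negligible while the per-frame centerlines
(extracted from automatically propagated, hence ragged, masks) carry
tangent noise — their 90th-percentile tangent error is tens of degrees —
which attenuated recovered strain by roughly a third. Terminal is
therefore the default; incremental remains available for sequences with
large rotations and clean per-frame masks.

**Centerline extraction.** Step 1 scores every mask voxel by an
erosion-depth transform (how many 6-connected erosions it survives — the
mask is eroded over its entire extent) and takes the geodesic path, with
step costs that strongly penalize leaving the erosion ridge, between the
two mutually farthest near-ridge voxels. Path points are recentered on
the local mask centroid (two mean-shift passes) and the cap-adjacent path
ends — where the ridge degenerates into a cone — are trimmed before
fitting. After the polynomial fit the curve is extended *straight along
the end tangents* until it exits the mask: without that extension every
end-cap voxel clamps onto the last centerline sample, and the arc
coordinates at a freely sliding (avulsed) end become meaningless.
Validation: on a solid cylinder the fitted line stays within 1 voxel of
the true axis with tangents within 5 degrees; on a half-torus tube the
curve stays within 1.5 voxels of the analytic arc.

**Block size.** The default block is $5^3$ voxels, not larger. The band
of the phantom (and the PRM at typical spacings) is only about 8 voxels
thick; a $9^3$ block straddles the shear layer at the muscle surface and
averages moving muscle with slower surroundings, which halved recovered
strain magnitudes in validation. Masked tracking (block statistics
restricted to the current segmentation, `propagate_sequence(...,
masked_tracking = TRUE)`) removes the remaining boundary contamination.

**Region cuts.** The two end regions together hold one third of the
muscle volume (each end one sixth, by sorted arc coordinate, exact by
voxel count); the mid region holds the rest. Regions are fixed on the
rest-frame mask and carried by material correspondence — they are
anatomical, not frame-dependent. The `s = 0` end of the centerline is the
end with the smaller first-axis coordinate and is labelled *right*
(ultrasound display convention places the patient's right on the image
left); the `orientation` flag flips the labelling.

**Exact Mann-Whitney U.** Cohorts are compared with
$U = \min(U_a, U_b)$ and a two-sided $p = P(U \le U_\mathrm{obs})$
computed by enumerating all $\binom{n_a + n_b}{n_a}$ group assignments
whenever that count is at most 200,000 — which covers 8-versus-10
($43{,}758$ assignments) in well under a second — falling back to the
normal approximation with mid-ranks, tie correction and continuity
correction. Shapiro-Wilk normality checks and Welch t-tests (for
demographic-style variables) are thin wrappers over the standard
implementations with explicit domain errors.

## The synthetic phantom

`generate_phantom()` builds the validation data: a half-annulus band
(default arc radius 20 mm, tube radius 4 mm, spanning 180 degrees) in a
$64^3$ volume at 1 mm spacing, imaged over 8 frames at 1.5 volumes/s with
a linear activation ramp from rest to full contraction. Scatterers
(1.5 per mm$^3$, Gaussian amplitudes) are placed uniformly at random;
those near the band move with the analytic motion field and each frame is
rendered as the absolute value of the PSF-blurred scatterer sum
(Gaussian PSF, $\sigma = 1$ mm) plus additive Gaussian noise at 10% of
the mean envelope.

The motion field is a tangential slide along the band: strain is
piecewise constant along the arc — mid section (two thirds of the arc)
at `peak_mid_strain` (default $-10\%$), end sections carrying the values
dictated by the anchoring — with cosine-tapered transitions (width 10% of
arc length) so the displacement is differentiable. For an intact band
both ends are anchored (zero displacement at both endpoints, which forces
the end sections to $+20\%$ when the mid is at $-10\%$); for an avulsed
band only the intact end is anchored and the avulsed end section carries
the mid's negative strain. Points move by rotation about the annulus
center, so material at radius $\rho$ sweeps a chord proportional to
$\rho$; the motion decays smoothly to zero over one tube radius outside
the band, so the tracker never faces a discontinuous field. Per-voxel
ground-truth displacement and strain, and the analytic centerline, are
returned alongside the rendered frames; everything is bit-reproducible
from `(spec, seed)`.

What the phantom does *not* emulate: attenuation, shadowing and other
depth-dependent image quality; speckle decorrelation from out-of-plane
motion and elevational beam width; probe pressure and whole-body motion;
anatomical shape variability; the return-to-rest half of the clinical
acquisition. Passing the phantom suite therefore demonstrates that the
estimator chain is correct and unbiased on honest speckle with known
truth — not that clinical accuracy equals phantom accuracy.

Cohort-level validation uses `generate_cohort_ratios()`: log-normal ratio
samples for two groups of 8 and 10 with medians 0.36 and 1.54 (the
group medians observed in the study this pipeline operationalizes) and a
log-scale spread of 0.8, chosen so that the group ranges reproduce the
reported spread of roughly one decade; the study does not print
individual ratios, so the spread is a modelling choice, stated here once.

## Numerical choices and degenerate inputs

* Strain windows need at least 4 valid members and an arc-coordinate
  sample variance of at least $10^{-6}\,\mathrm{mm}^2$; otherwise the
  voxel is undefined (never silently zero).
* The normalized ratio refuses a denominator below $10^{-9}$ (mid equal
  to the end average) with an explicit degenerate-denominator error — a
  zero-motion subject surfaces this error rather than an infinite ratio.
* NCC ties are broken toward the smaller displacement; a numerically
  perfect correlation peak (an exact integer match) skips subvoxel
  refinement, since the three-point fit would only be fitting speckle
  autocorrelation asymmetry.
* Volume readers refuse missing or non-positive voxel spacing rather than
  assuming 1 mm.
* Problem sizes used by the validation suite: unit tests run mostly on
  $48^3$ phantoms with 4 frames; the acceptance checks run the full
  $64^3 \times 8$ study conditions, including five seeds per condition
  for the ratio-separation check and 200 replicate cohorts for the
  test-calibration check.

## Known limitations

* The fiber-direction proxy is a single centerline tangent field; fiber
  dispersion across the muscle cross-section is not modelled.
* Strain is a scalar along the fiber; no full strain tensor or principal
  strains.
* The avulsed end of the band slides several millimetres; within about
  one tube radius of a free end, partial-volume mixing with the
  surroundings attenuates tracked motion even with masked blocks, which
  is the dominant residual error in avulsed-phantom recovery.
* DICOM input is not implemented; convert acquisitions to 4D NIfTI first.
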