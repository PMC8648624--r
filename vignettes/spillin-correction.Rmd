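---
title: "Bone spill-in correction for [18F]-NaF PET of abdominal aortic aneurysms"
author: "petbc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone spill-in correction for [18F]-NaF PET of abdominal aortic aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petbc)
```

## The problem

[18F]-sodium fluoride PET images microcalcification. In abdominal aortic
aneurysm (AAA) imaging the aneurysm wall sits directly anterior to the
spine, and bone takes up far more tracer than the wall. Because PET
resolution is finite (a few mm), activity from the hot vertebra "spills in"
to the adjacent aneurysm and inflates its apparent uptake, most strongly in
the posterior wall — which is exactly the region where rupture most often
originates, so simply cropping it out of the region of interest (ROI)
discards clinically relevant signal.

Two strategies are compared throughout this package:

* the conventional workaround: quantify an ROI that *excludes* the
  bone-proximal part of the aneurysm (`AAAexc`, built by
  `derive_aaa_exc()`), and
* a *background correction* (BC): remove the bone's contribution from the
  data model during reconstruction, so the whole-aneurysm ROI can be used.

Everything runs on synthetic 2D phantoms; no patient data is bundled or
required.

## The phantom

`phantom_spec()` / `generate_phantom()` build a single-slice abdominal
section: an elliptical soft-tissue body, a circular vertebral bone, an
aneurysmal aorta modelled as a hot wall annulus around a blood-filled
lumen, a separate normal-aorta segment, and a 2 cm^2 blood-pool reference
disc. The bone-surface-to-aneurysm-surface distance `gap_mm` is the key
geometric dial: `gap_mm = 0` is the contact configuration, and the detached
configuration uses 15 mm by default.

Default uptake levels are unitless SUV-like values — blood 1.0, normal
aorta 1.2, aneurysm wall 3.0, bone 6.0, soft tissue 0.3 — chosen so that
noise-free target-to-blood ratios and percent differences fall in the range
reported for clinical [18F]-NaF AAA studies (TBR of a few, aneurysm-vs-
normal-aorta differences on the order of 100%). CT values are 1000 HU
(bone), 40 HU (soft tissue), 30 HU (blood), −1000 HU (air). Regions are
piecewise constant and edge pixels are assigned by pixel-centre membership,
so region means are exact and mask invariants can be asserted without
tolerance.

What the phantom deliberately does *not* emulate: 3D geometry, anatomical
texture, intraluminal thrombus heterogeneity, respiratory/cardiac motion,
scatter and randoms. Passing tests therefore demonstrate the *mechanism*
(spill-in and its correction) under controlled conditions, not clinical
performance.

## The acquisition model

`build_system_model()` assembles a linear operator
`A = diag(att) %*% P %*% K`:

* `K` — isotropic Gaussian point-spread function applied in image space
  (default 4.4 mm full width at half maximum; sigma = FWHM/2.3548),
  implemented as a symmetric separable convolution,
* `P` — a 2D parallel-beam projector (default 96 angles over [0, pi),
  detector bin = pixel size, bins covering the image diagonal),
* `att` — per-ray attenuation factors `exp(-integral of mu)`, with mu at
  511 keV obtained from CT by a two-segment HU map
  (`mu_water = 0.0096/mm`; a shallower slope above 0 HU).

`P` is pixel-driven: each pixel projects its centre onto the detector and
splits its mass linearly between the two nearest bins. The two interpolation
weights always sum to one, so per-angle mass preservation is *exact* and the
backprojector is the exact matrix transpose — the adjoint identity
`<Ax, y> = <x, A'y>` holds to machine precision, which is what guarantees
monotone likelihood for the EM iterations. A ray-driven (Joseph)
interpolator was considered and rejected: with detector bins equal to the
pixel size its per-angle sums are not exactly preserved, which would turn
several exact invariants into approximate ones.

`simulate_counts()` scales the expected sinogram to a target total count
(default 5e5 per slice, giving maximum-voxel noise comparable to clinical
[18F]-NaF slices at this raster) and draws independent Poisson counts,
restoring the caller's RNG state afterwards.

## Reconstruction

`osem()` maximizes the Poisson likelihood of `y ~ Poisson(Ax + r)` by
ordered-subset expectation maximization:

```
x <- x * A_s'( y_s / (A_s x + r_s + eps) ) / A_s' 1
```

with `eps = 1e-10` guarding the ratio, subsets formed by dealing angles
round-robin in bit-reversed order (consecutive subsets see maximally
different directions), uniform initialization (value 1) inside the support,
and zero-sensitivity pixels frozen at zero. One subset gives plain MLEM,
and the test suite checks the two agree update-for-update against an
independently coded EM oracle. The PSF used during reconstruction is taken
from the `recon_config()`, not from the data-generating model, so the same
sinogram can be reconstructed with and without resolution modelling
(the "OSEM" vs "OSEM+PSF" variants; both forward and back steps use the
same kernel — a matched operator). The clinical 3 mm FWHM Gaussian
post-filter is a separate operation (`gaussian_postfilter()`), applied once
after the final iteration.

A known convergence property matters for interpretation: early-stopped EM
recovers contrast of small structures only partially. At the clinical
settings (21 subsets, 3 iterations, i.e. ~63 EM-equivalent updates) the
phantom's 6 mm wall mean reaches roughly 85% of its true value, and longer
runs approach the truth monotonically. The suite asserts the exact MLEM
fixed point at the truth, likelihood monotonicity and the OSEM-vs-MLEM
oracle agreement; absolute noise-free ROI-mean recovery at the clinical
iteration budget is checked at a 5% tolerance and documents how far
early stopping gets.

## Background correction

The BC variant (`reconstruct_bc()`) treats the bone as a *known background*
in the forward model rather than subtracting it from the counts (which
would create negative bins):

1. reconstruct the data without correction (OSEM+PSF),
2. segment bone from CT by thresholding at 150 HU and dilating one
   8-neighbourhood pass (the dilation absorbs segmentation edge error so
   rim activity is not attributed to the aneurysm),
3. forward-project the bone-restricted initial image into a background
   sinogram `b`,
4. re-run OSEM with additive term `b` and support restricted to non-bone
   pixels.

The output is exactly zero on the bone mask by construction. The bone
estimate is taken in a single pass; alternating refinement is possible in
principle but off by default, since the single pass already removes the
rim overshoot that drives ROI sensitivity. If segmentation yields an empty
mask the function warns and returns the uncorrected reconstruction.

## Quantification and statistics

For a target ROI T and the blood pool B, `uptake_metrics()` reports

* `SUVmax(T)`, `SUVmean(B)`,
* `cSUVmax = SUVmax(T) - SUVmean(B)`,
* `TBRmax = SUVmax(T) / SUVmean(B)`,

and `percent_difference(a, b) = 100 (a - b) / b` compares techniques or
regions; differences strictly above 25% are classed clinically significant
(`classify_significant()`, the EORTC-style rule). `spill_in_factor()`
splits the aneurysm into the bone-proximal ("prone") part and the rest and
reports the ratio of their maxima. In the study driver the prone distance
rides on top of the configured bone-aneurysm gap, so the bone-facing
portion is well defined in both contact and detached geometries.

The agreement layer mirrors standard clinical methodology: Bland–Altman
limits of agreement (`mean ± 1.96 SD`, sample SD with n−1), a paired t
test, Pearson correlation, Cronbach's alpha, and the single-measure
absolute-agreement intraclass correlation ICC(A,1) — two-way random
effects, with the F-based 95% confidence interval using Satterthwaite
degrees of freedom. ICC(A,1) was fixed (rather than a consistency ICC)
because the question is whether BC on the whole-aneurysm ROI can *replace*
the conventional excluded-ROI numbers, which is an absolute-agreement
question. P-values are reported, never used to gate pipeline behaviour.

Distances (ROI exclusion, prone region) are Euclidean between pixel
centres; coordinates are 0-based pixel indices scaled by the pixel size.
The default exclusion and prone distances are 8 mm, roughly twice the PSF
FWHM, and remain explicit configuration values.

## The replicate study

`run_study()` is the end-to-end driver: for each geometry (contact,
detached) and each replicate it simulates an acquisition, reconstructs with
the three algorithms, post-filters, and quantifies all ROIs; aggregation
reproduces the shape of the clinical comparison tables (AAA vs AAAexc per
algorithm with paired tests, percent difference vs the normal aorta with
limits of agreement and significance counts, spill-in factors by geometry,
and the agreement statistics between OSEM+PSF on AAAexc and BC on the whole
AAA). Per-replicate seeds are `master_seed + replicate`, shared across the
two geometries so they see matched noise; everything is reproducible from
the master seed alone.

Problem sizes were chosen to keep a full study on one core in the
low minutes: 128 × 128 pixels at 3 mm, 96 angles, 5e5 counts,
20 replicates. The unit-test fixtures use a 64-pixel version of the same
anatomy with 48 angles and 3 replicates.

## Known limitations

* 2D single-slice; no 3D, TOF, scatter, randoms, detector normalization or
  dead time. An optional additive sinogram term in `osem()` is the hook for
  scatter/randoms if ever needed.
* Spatially invariant PSF.
* Early-stopped EM under-recovers small-structure contrast at clinical
  iteration budgets (quantified above); comparisons *between* algorithms at
  matched settings are unaffected, which is why the study's conclusions are
  stated as orderings and agreements rather than absolute recoveries.
* The ICC confidence interval uses the standard F approximation; it is not
  bit-identical to every statistics package, but matches an independent
  implementation to printed precision in the tests.
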