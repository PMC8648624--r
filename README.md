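# petbc

Bone spill-in simulation and background-corrected OSEM reconstruction for
[18F]-NaF PET quantification of abdominal aortic aneurysms (AAA).

## The problem

[18F]-sodium fluoride PET highlights microcalcification in the aneurysm
wall, a candidate biomarker for AAA rupture risk. The abdominal aorta lies
directly against the spine, and bone accumulates far more tracer than the
aneurysm. With a scanner resolution of a few millimetres, bone activity
*spills in* to the adjacent posterior wall and inflates SUV-based
quantification — precisely in the region where posterior retroperitoneal
rupture originates. The conventional fix is to exclude the bone-proximal
part of the aneurysm from the region of interest (the `AAAexc` ROI), at the
cost of discarding clinically relevant signal and making results depend on
the delineation choice.

`petbc` implements, at desk scale and fully synthetically, the pipeline
needed to study and correct this effect:

* **digital phantoms** of the bone/aneurysm/blood geometry with a
  configurable bone-aneurysm gap (`phantom_spec()`, `generate_phantom()`);
* a **2D parallel-beam acquisition model** with CT-derived 511 keV
  attenuation, image-space Gaussian PSF and Poisson counting
  (`build_system_model()`, `forward_project()`, `simulate_counts()`);
* **OSEM/MLEM reconstruction** (default 21 subsets, 3 iterations) with
  optional PSF modelling, additive background term and support masking,
  plus the clinical 3 mm FWHM Gaussian post-filter (`osem()`,
  `gaussian_postfilter()`);
* the **background correction (BC)**: bone is segmented from CT
  (threshold 150 HU), its activity is forward-projected into a known
  additive background, and the image is re-reconstructed on the non-bone
  support, yielding a bone-free image (`reconstruct_bc()`);
* **ROI quantification**: `cSUVmax = SUVmax(T) − SUVmean(B)`,
  `TBRmax = SUVmax(T)/SUVmean(B)`, percent differences with the 25%
  clinical-significance rule, spill-in factors and line profiles;
* **agreement statistics**: Bland–Altman limits of agreement
  (`d̄ ± 1.96·SD`), paired t, Pearson, Cronbach's α and the single-measure
  absolute-agreement ICC(A,1) with F-based confidence interval;
* a **replicate study driver** (`run_study()`) that reproduces the whole
  comparison — OSEM vs OSEM+PSF vs OSEM+PSF+BC, AAA vs AAAexc, contact vs
  detached geometry — from a single master seed.

## Worked example

```r
library(petbc)

# 1. A contact-geometry phantom: hot bone touching the aneurysm wall
spec <- phantom_spec(gap_mm = 0)
ph <- generate_phantom(spec)

# 2. Simulate one acquisition through the attenuated, PSF-blurred system
geom  <- default_geometry(ph$activity)
model <- build_system_model(ph$ct, geom)
y <- simulate_counts(forward_project(ph$activity, model),
                     total_counts = 5e5, seed = 6)
model <- petbc:::with_count_scale(model, attr(y, "scale"))

# 3. Reconstruct with and without background correction
fit_psf <- osem(y, model, recon_config())          # OSEM + PSF
fit_bc  <- reconstruct_bc(y, ph$ct, model)         # OSEM + PSF + BC
fit_bc
#> <osem_fit> algorithm osem-psf-bc: 21 subsets x 3 iterations (PSF 4.4 mm)
#>   image 128 x 128 @ 3 mm, max 4.13; logLik 1.57455e+06
img_psf <- gaussian_postfilter(fit_psf$image)
img_bc  <- gaussian_postfilter(fit_bc$image)

# 4. Quantify the aneurysm with both ROI conventions
aaa_exc <- derive_aaa_exc(ph$masks$aaa, ph$masks$bone,
                          exclusion_mm = 8, pixel_mm = spec$pixel_mm)
uptake_metrics(img_psf, ph$masks$aaa, ph$masks$blood)
#> SUVmax(T) 5.083  SUVmean(B) 0.902  cSUVmax 4.181  TBRmax 5.633
uptake_metrics(img_psf, aaa_exc, ph$masks$blood)
#> SUVmax(T) 3.837  SUVmean(B) 0.902  cSUVmax 2.935  TBRmax 4.252
uptake_metrics(img_bc, ph$masks$aaa, ph$masks$blood)
#> SUVmax(T) 3.811  SUVmean(B) 0.907  cSUVmax 2.904  TBRmax 4.201
uptake_metrics(img_bc, aaa_exc, ph$masks$blood)
#> SUVmax(T) 3.811  SUVmean(B) 0.907  cSUVmax 2.904  TBRmax 4.201

spill_in_factor(img_psf, ph$masks$aaa, ph$masks$bone, prone_mm = 8)
#> spill-in: max 5.083 (bone-proximal) vs 3.837 (rest) -> factor 1.32
```

Reading the numbers: with OSEM+PSF the whole-aneurysm SUVmax (5.08) is
dominated by a bone-proximal voxel — spill-in inflates it 32% above the
rest of the wall — and the value drops to 3.84 once the bone-proximal zone
is excluded, so the answer depends on the ROI. With background correction
the bone is removed from the data model and both ROI conventions return
the same quantification (3.81): the BC image is robust to the delineation
choice.

`run_study(study_config())` repeats this over 20 noise replicates and both
geometries and aggregates the comparison tables (paired AAA-vs-AAAexc
tests per algorithm, percent difference vs the normal aorta with limits of
agreement, spill-in factors, and ICC/α agreement between OSEM+PSF on
AAAexc and BC on the whole AAA).

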