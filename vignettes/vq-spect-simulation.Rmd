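---
title: "Simulating dual-isotope lung V/Q SPECT with ground-truth defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating dual-isotope lung V/Q SPECT with ground-truth defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ventilation/perfusion (V/Q) SPECT of the lungs maps regional lung function:
an inhaled Kr-81m gas study shows where air goes, a Tc-99m-MAA study shows
where blood goes. Quantifying functional lung volumes from these images —
for pulmonary embolism burden (the pulmonary vascular obstruction index,
PVOI) or radiotherapy planning — is held back by two things. First,
perfusion is physiologically non-uniform: in a supine patient gravity
drives an anterior-to-posterior intensity gradient, so a fixed intensity
threshold is normal ventrally and pathological dorsally. Second, real
patients provide no ground truth against which a delineation algorithm can
be scored.

`vqspect` addresses both with a fully synthetic, seeded pipeline: a
tissue-coded digital thorax phantom, activity painting that includes the
gravity gradient, a simplified but physically explicit SPECT forward
model, OSEM reconstruction, and voxelwise Z-score scoring against a
synthetic normal database. Because the source maps are constructed, every
defect has exact ground truth — its mask, its relative concentration, and
its analytic PVOI.

## The model chain

### Phantom

A CT Hounsfield-unit volume (real, or from the bundled parametric thorax
generator) is segmented by HU intervals into six classes: outside air,
lung, bronchi, fat, soft tissue, bone. The conventional cutpoints
(air < −950 HU, lung [−950, −400), fat [−400, −30), soft tissue
[−30, 150), bone ≥ 150) are defaults, not fitted values, and are
configurable. Air is split into *outside air* versus *intrathoracic
airway* by 6-connected component labeling against the volume border:
border-connected air is outside the body, enclosed air is airway. This is
deterministic and needs no manual editing.

Each tissue code maps to a density and to linear attenuation coefficients
at 140 keV (Tc-99m) and 190 keV (Kr-81m). The coefficients use
water-equivalent scaling by density, mu(E) = (mu/rho)_water(E) · rho, with
(mu/rho)_water = 0.1537 cm²/g at 140 keV and 0.1396 cm²/g at 190 keV.
These are physics constants; for bone the water-equivalent approximation
slightly underestimates mu, which is acceptable at this model's fidelity
and is user-overridable via the tissue table.

Code volumes fit 8 bits and can be resampled to a coarser simulation grid
(e.g. 128×128×108 at 3.92×3.92×3.59 mm) by per-voxel majority vote — codes
are categorical and are never numerically interpolated. Ties break to the
smallest code, deterministically.

### Sources

*Ventilation*: Kr-81m (190 keV, abundance 1.0) is modeled as a stationary
homogeneous gas — it is continuously inhaled and exhaled (13 s half-life),
so the package paints a uniform 55 kBq/mL over lungs *and* airways with no
decay during the acquisition.

*Perfusion*: Tc-99m-MAA (140 keV, abundance 0.885) lodges in pulmonary
capillaries, so airways get zero. The gravity gradient is modeled by
dividing the joint lung bounding box along the anterior–posterior axis
into 16 coronal slabs of near-equal thickness (one partition for both
lungs — there is a single gravity axis; remainder voxels go to the
posterior-most slabs). Slab concentrations default to a linear ramp from
43 kBq/mL (anterior) to 65 kBq/mL (posterior). Only the two endpoints are
clinically established constants here; the intermediate plane values in a
real database are a fitted curve that is not published, so linear
interpolation is the least-assuming default and the full 16-vector can be
supplied instead. Equal-thickness (rather than equal-volume) slabs are
used because plane *width* is the physically meaningful quantity for a
gravity gradient (about 1 cm per plane at clinical grids).

*Defects*: a defect is a mask plus a relative concentration in [0, 1);
insertion multiplies in-mask activity and leaves everything else
bit-identical. The parametric wedge generator approximates a segmental
territory: lung voxels inside a cone apexed near the hilum, default
half-angle 25°, which yields roughly one of ~19 bronchopulmonary segments
(about 5% of total lung volume on the default thorax). Ground-truth PVOI
is defined as the activity-weighted perfusion loss,
1 − Σ(defect map)/Σ(normal map) over the lungs. No standard formula is
printed in the clinical literature at this granularity; this is the
natural activity-space reading of "fraction of pulmonary perfusion lost",
and it makes disjoint defects exactly additive.

### Forward model

The Monte-Carlo transport of a full simulator is deliberately replaced by
an analytic chain — the scientific object here is the *model and its
validation*, not the photon transport engine, and the analytic chain is
deterministic and desk-scale:

- parallel-beam line integrals of activity attenuated along the exit path
  (exclusive path integral, so a separated slab with ∫mu = ln 2 halves
  counts exactly);
- a depth-dependent Gaussian detector response
  FWHM(d) = sqrt(FWHM_int² + (a·d + b)²), defaults FWHM_int = 3.8 mm,
  a = 0.055, b = 1 mm (≈7.5 mm system FWHM at 10 cm, a plausible
  medium-energy collimator, not a measured camera);
- per energy window, expected counts are
  geometric_fraction · primary + scatter_fraction · (primary ⊛ broad
  Gaussian), with Kr-81m downscatter added into both Tc windows. The four
  windows are the clinical dual-isotope set ([109.9, 129.5],
  [129.5, 150.5], [150.7, 177.6], [177.6, 206.4] keV). Scatter and
  downscatter fractions (0.30 in-window, 0.15 Kr→Tc-photopeak, 60 mm
  kernel) are stated stand-ins chosen for plausible window ratios — they
  are configuration, not calibration;
- Poisson noise last, after optional rescaling of the expectation to a
  target total count (absolute sensitivity is a single scalar and is
  irrelevant once counts are rescaled).

The clinical non-circular orbit is simplified to a circular 30 cm orbit.
Acquisition defaults are 128 projections at 10 s each, step-and-shoot
(independent static projections); the test and demo configurations use 32
projections to stay desk-scale, which is stated wherever it is done.

Two numerical choices matter. Volume rotation uses bilinear interpolation
as an explicit sparse operator; for the *activity* (an extensive
quantity) the package uses the conservative transpose ("splat") form, so
total counts are conserved exactly away from the volume edge, while the
attenuation map (intensive) uses the gather form. The detector is sampled
on the simulation grid's in-plane pitch rather than resampled to the
4.7 mm camera pitch; the camera pitch is carried as metadata. This keeps
the projector pair exactly matched without a detector-resampling operator.

### Reconstruction

Generic OSEM stands in for the vendor chain: default 4 iterations, 8
subsets (bit-reversed subset order), optional attenuation correction from
the phantom-derived mu map at the window's photopeak energy, optional
modeling of the depth-dependent response in the projector pair, and an
8.4 mm Gaussian post-filter applied once after the last iteration.
Dual-energy-window (DEW) scatter correction subtracts
k · (W_photo/W_scatter) · scatter-window from the photopeak with
pixelwise zero-clipping, k = 0.5 by default; it is applied to the data
*before* iterating, the simplest faithful reading of a vendor chain
(whether the vendor applies it inside the iterations is not public; the
choice is recorded in each volume's provenance). The triple-energy-window
method is deliberately not provided: normal databases in this setting are
DEW-based, and scoring against them with a different correction would
bias the Z-scores.

Because forward and back projectors are literal transposes of one
another, MLEM monotonicity holds: the Poisson log-likelihood is
non-decreasing over full iterations, and every update preserves
non-negativity (EM ratios are floored at 1e-12; voxels with zero
sensitivity stay zero). Initialization is a uniform positive volume on
the sensitive support.

### Z-score validation

Reconstructions are mean-normalized and compared voxelwise to a normal
database: z = (value − MEAN)/SD. Statistics (mean, population SD, % of
voxels beyond ±1) are computed in an ROI eroded 0.5 cm inside the lung
boundary to avoid partial-volume artifacts; at 4–6 mm voxels that margin
is one voxel (the erosion radius is the margin over the pitch rounded to
the nearest integer, minimum one voxel — a ceiling rule would give two
voxels at 3.92 mm pitch and contradict the intended one-pixel margin).
The normalization region is not standardized; the package uses the eroded
lung ROI consistently for the database and for test volumes, because
internal consistency of normalization is what the Z-score requires.

The 73-case clinical normal database that motivates this design is not
redistributable, so a seeded synthetic builder stands in: n subjects are
simulated end to end, each perturbed by (i) a global log-normal activity
scale (log-SD 0.1), (ii) Gaussian jitter of the two gradient endpoints
(SD 3 kBq/mL) — the anterior-posterior gradient being the dominant mode
of real inter-subject variability — and (iii) a smooth multiplicative
field (SD 0.05, 3 cm correlation length) for residual regional
variability. MEAN and SD maps use the population SD. Voxels whose SD
falls below 1e-3 of the in-ROI mean are excluded from statistics (a
degenerate zero-variability database would otherwise divide by ~0).

**What a green test establishes.** The synthetic database shares its
generative process with the held-out test cases, so the self-consistency
checks (mean z near 0, SD z near 1, defect drives in-defect z below −1)
validate the *pipeline's internal coherence* — normalization, database
construction and scoring composing correctly — not agreement with real
patients. Clinical Table-style Z-score values against 73 real cases are
out of reach by construction, and the package does not claim them. What
the synthetic model does not emulate: respiratory motion, caudo-cranial
gradients, fissure and segmental-contour signs, MAA particle transport,
septal penetration, energy resolution sampling, dead time.

## Tunable parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| Ventilation concentration | 55 | kBq/mL | clinical protocol value |
| Gradient endpoints | 43 → 65 | kBq/mL | clinical anterior/posterior planes |
| Coronal planes | 16 | — | ~1 cm per plane at clinical grids |
| Defect relative concentration | 0.5 | — | worked 50% segmental example |
| Energy windows | four presets | keV | dual-isotope protocol |
| Projections / time | 128 / 10 | — / s | clinical protocol (32 in demos) |
| Orbit radius | 30 | cm | circular simplification |
| PSF (int, a, b) | 3.8, 0.055, 1 | mm, mm/mm, mm | plausible MELP stand-in |
| Scatter / downscatter fractions | 0.30 / 0.15 | — | stated stand-ins |
| OSEM iterations × subsets | 4 × 8 | — | clinical chain |
| DEW k | 0.5 | — | classic dual-window estimate |
| Post-filter FWHM | 8.4 | mm | clinical chain |
| ROI margin | 0.5 | cm | one voxel at clinical pitch |
| Database n, variability | 20; 0.1/3/0.05 | —; log, kBq/mL, frac | desk-scale stand-in |

## Known limitations

- The forward model is analytic: no photon-level scatter angles, no septal
  penetration, no backscatter. Window cross-talk is parametric.
- The synthetic thorax is geometric (ellipsoids, cylinders); it exercises
  segmentation, gradients and ROIs, not anatomical realism.
- Absolute sensitivity and energy resolution are inputs, not predictions.
- Z-score realism is self-referential (see above); only the printed model
  parameters and the physics/reconstruction invariants are externally
  anchored.
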