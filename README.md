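# vqspect

Desk-scale simulation of **dual-isotope lung V/Q SPECT** with exact
ground-truth perfusion defects, for developing and benchmarking
functional-lung delineation methods.

Paired ventilation/perfusion SPECT (inhaled ⁸¹ᵐKr gas for ventilation,
injected ⁹⁹ᵐTc-MAA for perfusion) maps regional lung function, but
quantifying functional volumes — e.g. the pulmonary vascular obstruction
index (PVOI) in pulmonary embolism — is hampered by the gravity-driven
anterior-to-posterior perfusion gradient and by the absence of ground
truth in real patients. `vqspect` provides a fully synthetic, seeded
pipeline in which both problems are solved by construction:

1. **Phantom** — a CT HU volume (real, or from the bundled parametric
   thorax generator) is segmented into six tissue classes (outside air,
   lung, bronchi, fat, soft tissue, bone), 8-bit coded, with attenuation
   per tissue at 140 and 190 keV, and resampled by majority vote to a
   simulation grid (e.g. 128×128×108 at 3.92×3.92×3.59 mm).
2. **Sources** — ventilation: uniform 55 kBq/mL over lungs + airways;
   perfusion: sixteen coronal slabs ramping 43 → 65 kBq/mL anterior →
   posterior, zero in airways. Wedge-shaped segmental defects multiply
   in-zone activity by a known fraction (e.g. 50%), with analytic PVOI
   `1 − Σ(defect)/Σ(normal)`.
3. **Acquisition** — analytic attenuated projections with a
   distance-dependent Gaussian collimator response
   `FWHM(d) = √(FWHM₀² + (a·d + b)²)`, four clinical energy windows,
   parametric in-window scatter and Kr→Tc downscatter, count rescaling
   and Poisson noise.
4. **Reconstruction** — OSEM (4 it × 8 subsets, matched projector pair,
   optional attenuation correction, dual-energy-window scatter
   correction, 8.4 mm Gaussian post-filter).
5. **Validation** — voxelwise Z-score
   `z = (value − MEAN)/SD` against a seeded synthetic normal database,
   with statistics in an ROI eroded 0.5 cm inside the lung boundary.

See the vignette (`vignettes/vq-spect-simulation.Rmd`) for the model, its
assumptions and every tunable parameter.

## Worked example

A JSON config drives the whole chain. With `config.json`:

```json
{
  "seed": 5,
  "grid": {"shape": [48, 48, 32], "voxel_mm": [8, 8, 12]},
  "gradient": {"c_first": 43, "c_last": 65, "n_planes": 16},
  "acquisition": {"n_projections": 16, "target_total_counts": 500000},
  "recon": {"iterations": 2, "subsets": 4},
  "database": {"n_subjects": 8},
  "zscore": {"margin_cm": 0.5}
}
```

```sh
Rscript inst/cli/vqspect.R run --config config.json --out run_normal
# mean z 0.021 (SD 1.225); %>+1 18.5; %<-1 18.4; ROI 2476 voxels
```

A held-out normal case scores near zero mean z against the synthetic
database — the pipeline is self-consistent. Adding a 50% segmental wedge
defect (`"defect": {"enabled": true, "half_angle_deg": 25,
"relative_concentration": 0.5}`):

```sh
Rscript inst/cli/vqspect.R run --config config_defect.json --out run_defect
# mean z 0.063 (SD 1.713); %>+1 25.4; %<-1 17.2; ROI 2476 voxels
# ground-truth PVOI 0.0291
```

The defect inflates the Z-score spread and tails while the exact PVOI
(2.9% of perfusion lost: a ~5%-of-lung territory at 50% concentration) is
reported from the source maps — the ground truth a delineation method
would be scored against. Each run writes every intermediate volume
(phantom codes, source maps, database MEAN/SD, normalized reconstruction)
plus `stats.json` and a `manifest.json` with seeds and config echo;
re-running the same config + seed reproduces all of them.

The same stages are plain R functions (`make_synthetic_thorax`,
`segment_hu_volume`, `build_perfusion_source`, `insert_defect`,
`simulate_acquisition`, `osem_reconstruct`, `build_synthetic_normal_db`,
`zscore_stats`, ...) for scripted use.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the measured
impulse-response FWHM of the default reconstruction post-filter (a
single-voxel impulse on a 1 mm grid, half-maximum crossings located by
linear interpolation) and writes it as JSON.

## Scope notes

The Monte-Carlo photon transport of a full simulator is deliberately
replaced by the analytic chain above, and the clinical 73-case normal
database by the seeded synthetic builder; Z-score self-consistency
therefore validates the pipeline's internal coherence, not agreement with
real patients. Respiratory motion, caudo-cranial gradients,
fissure/contour signs and MAA particle transport are out of scope.
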