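# audtopo

Topographic mapping of **spectral frequency** (tonotopy) and
**amplitude-modulation rate** (periodotopy) in primate auditory cortex
from sparse-design BOLD fMRI, with per-field gradient statistics, and a
synthetic-data generator that stands in for undeposited macaque scans.

## Who this is for

Auditory neuroimagers who want a tested, end-to-end reference
implementation of the classic sparse-sampling mapping analysis — and a
way to validate it against planted ground truth — rather than a one-off
collection of scripts.

## What it computes

1. **Sparse-design GLM.** One volume per 10 s (stimulus in the 9 s
   silent gap), alternating with silent baselines. Per voxel,
   `value = Σ_c β_c·1[condition c] + drift (DCT, period > 300 s) + const`,
   after 2 mm FWHM smoothing and global scaling to a mean of 100, so β_c
   is the percent-signal-change response of condition *c* vs baseline and
   t_c = β_c/SE its t-value. Voxels are kept where the omnibus F-test of
   all conditions has p < 0.001 (Bonferroni optional).
2. **Feature maps.** Contrast maps on betas — mean(128, 512 Hz) −
   mean(0.5, 2 Hz) for rate; (8–16 kHz) − (0.5–1 kHz) for frequency —
   and best-rate / best-frequency maps as the argmax of t-values (ties to
   the lower condition value).
3. **Surface projection.** Vertex value = mean of in-mask voxels whose
   centres lie within a 1.6 mm sphere (majority vote for labels).
4. **Gradient statistics.** Each field is flattened to (u, v) with
   0° = anterior, 90° = lateral (right hemispheres mirrored); the map
   gradient is the OLS plane `b0 + bu·u + bv·v` with direction
   `atan2(bv, bu)` in [0°, 360°), R², and the F-test on (2, n−3) df. The
   relative angle between the frequency and rate gradients is
   `α = min(|d1−d2| mod 360, 360 − |d1−d2| mod 360) ∈ [0°, 180°]`,
   aggregated into a per-field table with Average and Std-dev rows
   (plain mean, sample SD).
5. **Phase-encoded mapping.** Nine half-octave tones (500–8000 Hz) in
   2 s blocks, 30 s cycles, presented low-to-high and high-to-low at
   TR 1.4 s; after 0.02–0.1 Hz zero-phase band-pass and percent-signal-
   change conversion, the circular cross-correlation lag between the two
   run types is `4k − 16` s for a voxel preferring ladder step *k*, so
   decoding the lag yields the preferred frequency with the haemodynamic
   delay cancelled.
6. **Synthetic cortex.** A flat cortical sheet with the A1/R/RT core and
   CL/ML/AL/CM belt mosaic, concentric iso-rate bands
   (`128·2^(−d/3 mm)` Hz, clipped to [0.5, 128]), per-field tonotopic
   axes with reversals at the A1/R and R/RT borders, log-Gaussian tuning
   (1.5 octave SD, 1 % amplitude), and seeded Gaussian noise — the A1
   frequency/rate gradient directions are planted at 165°/53°
   (relative angle 112°).

## Worked example

```r
library(audtopo)

surf  <- make_surface(sheet_spec())                      # 30 x 20 mm sheet
truth <- make_ground_truth(surf$mesh, surf$parcellation) # planted maps

rate <- run_sparse_experiment(truth, surf$mesh, "rate", 540,
                              noise_params(sd = 6.7, seed = 1),
                              schedule_seed = 1001)
freq <- run_sparse_experiment(truth, surf$mesh, "frequency", 720,
                              noise_params(sd = 6.7, seed = 2001),
                              schedule_seed = 3001)

a1 <- flatten_field(surf$mesh, surf$parcellation, "A1")
ff <- fit_gradient(a1, freq$vertex_values)
rf <- fit_gradient(a1, rate$vertex_values)
ff
#> <gradient_fit> direction 165.4 deg, R^2 0.96, p <1E-16, n 98
rf
#> <gradient_fit> direction 60.3 deg, R^2 0.71, p <1E-16, n 95
relative_angle(ff$direction_deg, rf$direction_deg)
#> [1] 105.0944
```

The frequency-contrast gradient in A1 points postero-laterally (165°,
matching the planted 165°), the rate-contrast gradient antero-laterally
(60°, planted 53°), and their relative angle α ≈ 105° says the two maps
cross well away from parallel — the orthogonal-ish organisation the
analysis is built to quantify. Across ten replicate sessions the mean
recovered α is 120.0° (SD 10.7°) against a planted 112°.

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow — `01_simulate_study.R` (synthesise both hemispheres
and both sparse sessions), `02_sparse_glm_maps.R` (GLM, masks, feature
maps), `03_gradient_table.R` (the per-field α table),
`04_phase_mapping.R` (phase-encoded decoding across haemodynamic
delays), `05_parameter_recovery.R` (replicate-session recovery) — and
write their tables under `results/`. `run_pipeline(default_config())`
performs stages 1–3 in one call with every seed explicit in the config.

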