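---
title: "Mapping frequency and amplitude-modulation-rate topographies from sparse BOLD data"
author: "audtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping frequency and amplitude-modulation-rate topographies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audtopo)
```

## The scientific problem

Natural sounds vary along two fundamental dimensions: spectral content
(frequency) and temporal envelope (amplitude-modulation rate, AM rate). In
primate auditory cortex, frequency is mapped topographically (tonotopy)
within each field, with gradient reversals marking the borders between the
core fields A1, R and RT. Whether AM rate is likewise mapped — and how its
gradient is oriented relative to the tonotopic gradients — is the question
this pipeline quantifies. The organisation it models has preferred AM rate
arranged in approximately concentric iso-rate bands spanning several
fields, so that within A1 the rate gradient crosses the tonotopic gradient
at roughly (but not exactly) a right angle, with the departure from
orthogonality summarised by the relative angle $\alpha \in [0^\circ,
180^\circ]$ between the two fitted gradient directions.

The package implements the complete analysis as reusable, tested
functions, and pairs it with a synthetic-data generator because the
original macaque scans are not publicly deposited. Everything the
analysis claims is therefore demonstrated on data with known ground
truth.

## The analysis model

### Sparse-design GLM

The sparse experiments acquire one volume every 10 s (1 s acquisition,
9 s silent gap, stimulus in the gap), alternating stimulus and silent
baseline volumes; a 540-volume AM-rate session gives 45 volumes for each
of the six rates (0.5–512 Hz, octave-quadrupling), a 720-volume frequency
session 120 volumes for each of three noise bands (0.5–1, 2–4,
8–16 kHz). Because each volume is a single sample of the evoked
response, the design matrix is an indicator regression, not an
HRF-convolved one:

$$y_t = \sum_c \beta_c \, \mathbb{1}[\text{condition}_t = c]
      + \gamma_0 + \sum_k \gamma_k \cos\!\big(\pi k (t + \tfrac12)/N\big)
      + \varepsilon_t .$$

The silent baseline is the implicit intercept, so $\beta_c$ is the
stimulus-vs-baseline response and $t_c = \beta_c / \mathrm{SE}(\beta_c)$
its t-value. The discrete-cosine columns implement the 300 s high-pass
filter inside the model (keeping the degrees of freedom exact) — every
basis function with period $2T/k$ above the cutoff is included. An
arbitrary-phase slow cosine is absorbed exactly if it lies on the basis
grid and to within about 2 % of its amplitude otherwise (edge leakage of
the truncated cosine expansion; see the tests). Volumes are smoothed
with a 2 mm FWHM Gaussian and globally scaled so each volume's in-brain
mean is 100, which makes the betas read as percent signal change.

Per-volume global scaling deserves a caveat that matters for synthetic
data: it subtracts each condition's *spatial-mean* response from that
condition's betas. In a real acquisition the auditory cortex is a small
fraction of the recorded volume and the offset is negligible; in a
synthetic grid that consisted only of responsive voxels it would eat most
of the omnibus power. The default generator therefore embeds the
responsive sheet in a silent surround (6 mm in-plane margin, 9 slices),
making it roughly a third of the grid — similar in spirit to the real
recordings. Contrast maps are unaffected either way, because the offset
is constant across voxels within each condition.

Voxels are retained where the omnibus F-test of all condition
coefficients (jointly zero vs the drift-plus-constant reduced model) has
p < 0.001, uncorrected, with Bonferroni over tested voxels available as
the family-wise-error option. Degenerate cases are handled explicitly:
an exactly-fitted (noise-free) responding voxel gets omnibus p = 0 and a
finite t proportional to its beta (a variance floor replaces the zero
residual variance), while an exactly constant voxel gets p = 1 and drops
out of every map.

### Feature maps

Two map types summarise the fitted responses, and they deliberately use
different statistics: **contrast maps** subtract *betas* — mean of the
two highest rates (128, 512 Hz) minus mean of the two lowest (0.5, 2 Hz),
intermediate rates ignored; highest frequency band minus lowest for the
frequency experiment — while **best maps** take the argmax over
*t-values*, with exact ties broken toward the lower condition value. The
contrast sign convention is high-minus-low and is recorded in the map's
provenance, so a display can flip it without ambiguity.

### Surface projection

Volume maps are projected onto the triangulated cortical sheet by
averaging, for each vertex, the in-mask voxels whose centres lie within a
1.6 mm sphere (majority vote for label maps, ties toward the lower
condition). Membership is by voxel centre, not partial volume, which
makes the operation exactly testable against a brute-force enumeration.
The projection is restricted to the omnibus mask so baseline-only voxels
never dilute vertex values; vertices without any qualifying voxel are
missing rather than zero.

### Gradient statistics

Each analysed field (A1, R, CL by default) is flattened onto its best-fit
plane (principal axes of the vertex scatter), with the in-plane axes
rotated so $+u$ points anterior and $+v$ lateral; right-hemisphere
meshes carry a mirrored lateral axis, so the same frame applies to both
hemispheres and their rows are directly comparable. The map gradient is
the least-squares plane $value = b_0 + b_u u + b_v v$; its direction is
$\mathrm{atan2}(b_v, b_u)$ reported in $[0^\circ, 360^\circ)$ — a full
direction, not an axis, because relative angles above $90^\circ$
(anti-parallel organisation) are scientifically meaningful. $R^2$, the
F-test of $(b_u, b_v)$ on $(2, n-3)$ degrees of freedom, and $n$
accompany every fit; p-values below $10^{-16}$ are printed as `<1E-16`.
The relative angle is $\alpha = \min(|d_1 - d_2| \bmod 360, 360 - |d_1 -
d_2| \bmod 360)$.

Summary tables append per-field Average and Std-dev rows using plain
arithmetic means and the sample SD — not circular statistics — because
that is how the published per-hemisphere rows aggregate (the printed A1
average, 118.7, is exactly the arithmetic mean 712/6 of the printed
$\alpha$ values). A single-row field reports its SD as missing. Best
maps can be fed through the same regression on their ordinal condition
indices; a field whose vertices share a single best condition has no
gradient and raises an error, matching how such fields are treated in
practice.

### Phase-encoded mapping

The continuous experiment presents nine half-octave tones (500–8000 Hz)
in 2 s blocks — an 18 s progression followed by 12 s of silence, the 30 s
cycle repeated 15 times within a 343-volume run at TR 1.4 s — in both
low-to-high and high-to-low order. Each voxel series is band-passed
(0.02–0.1 Hz, order-2 Butterworth applied forward and backward, i.e.
zero-phase) and converted to percent signal change about its pre-filter
mean; the series is demeaned before filtering because the baseline
offset would otherwise dominate the filter's edge transients.

A voxel preferring ladder step $k$ (0-based) responds $2k$ s into the
low-to-high progression and $2(8-k)$ s into the high-to-low one, so the
cross-correlation lag between the runs is $4k - 16$ s and the
haemodynamic delay, common to both runs, cancels. The default estimator
averages each run over its stimulus cycles on a 0.2 s phase grid before
circularly cross-correlating (equivalent for periodic signals and less
noisy; full-series correlation at TR resolution is available as
`method = "full"`), and refines the peak by parabolic interpolation.
One subtlety is unavoidable: the measured lag is circular within half a
cycle (±15 s) while the model lags span ±16 s, so the extreme steps
alias (−16 s appears as +14 s). The decoder resolves this by choosing
the ladder step whose model lag is nearest to the measured lag modulo
one cycle; since model lags are 4 s apart and the alias error is 2 s,
all nine steps decode exactly in noiseless simulation, for any
haemodynamic delay between 0 and 6 s.

Voxels whose peak correlation falls below a threshold (default 0.2)
remain unassigned. This threshold is a configurable convention, not a
calibrated significance level: band-passed noise is smooth, so its
maximal circular correlation under the null is large (median ≈ 0.17,
95th percentile ≈ 0.29 for full-series correlation in our simulations,
and much larger for cycle-averaged profiles, which retain only three
passband harmonics). The tests therefore assert the measured separation
— true responses correlate above 0.9, nulls mostly below 0.2 with the
full-series method — rather than a near-perfect rejection rate.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

* **Geometry.** The superior temporal plane is idealised as a flat
  30 × 20 mm sheet triangulated at 1 mm, embedded at the axial centre of
  a 1 mm isotropic voxel grid with a 6 mm silent margin and 9 slices.
  Curvature is deliberately out of scope: a flat sheet makes the
  flattening step exact and the gradient oracle analytic. Right
  hemispheres are mirror images of left ones.
* **Parcellation.** An idealised geometric mosaic: A1, R, RT form the
  core band posterior-to-anterior at mid mediolateral position; CL, ML,
  AL form the lateral belt strip; CM sits postero-medially. Every field
  is non-empty and connected by construction. Parcellation is fixed, not
  derived from reversal detection — the reversals are still planted and
  testable, but border placement is not a claim under test.
* **Planted maps.** Preferred AM rate decays concentrically,
  $r(d) = 128 \cdot 2^{-d/\lambda}$ Hz clipped to $[0.5, 128]$ with
  $\lambda = 3$ mm of distance $d$ from a single high-rate centre (512 Hz
  is deliberately absent: responses that fast are barely represented).
  Log2 preferred frequency is affine along each field's axis, spanning
  0.5–16 kHz, with the axis reversing across the A1/R and R/RT borders.
  The default angles plant the A1 frequency/rate gradient directions at
  165°/53° — the published A1 column averages — so the planted relative
  angle is 112°. In the package's angle frame (0° = anterior, 90° =
  lateral, high-minus-low contrasts) this places the high-rate centre at
  bearing 53° from the A1 centroid. The published table reports angle
  magnitudes whose signs are not fully recoverable, so a frame choice
  was unavoidable; this one reproduces the published numbers exactly
  where they are arithmetic and preserves the concentric, monotone-decay
  and reversal structure everywhere.
* **Responses and noise.** Voxels inherit tuning from the nearest vertex
  within 2 mm (guaranteeing the 1.6 mm projection sphere finds signal);
  more distant voxels are pure baseline. The response is a Gaussian in
  log2 stimulus value with 1.5-octave SD — the study gives no neural
  tuning model, so a standard log-Gaussian was chosen — scaled to a 1 %
  peak signal change on a baseline of 100. Noise is i.i.d. Gaussian
  (optional AR(1)), default SD 6.7, chosen so the per-condition SNR
  after averaging 45 volumes is about 1 ($6.7/\sqrt{45} \approx 1$);
  response amplitude and noise level are calibration conventions, not
  published facts. Identical seeds give bit-identical series.
* **Phase runs.** The neural response is a boxcar in the voxel's
  preferred 2 s block each cycle, convolved with a gamma HRF peaking at
  the configured delay (shape delay+1, scale 1 s; delay 0 degenerates to
  the boxcar), sampled at TR. Cycle 1 starts at t = 0 and the trailing
  ~30 s of the run is silence.

### What the generator does and does not emulate

It emulates the acquisition geometry and timing, balanced sparse
schedules, tuning-curve-driven condition responses, hemispheric
mirroring, and the spatial structure of both topographies. It does not
emulate gyral curvature, vascular or physiological noise, motion,
session-to-session realignment error, or field-strength artefacts.
Passing tests therefore demonstrate that the *analysis* is correct and
recovers planted structure at realistic SNR — not that the analysis is
robust to every artefact of real data.

## Numerical choices and measured behaviour

* Smoothing kernels are truncated at 3 SD and edge-renormalised, so a
  constant volume is exactly preserved.
* The GLM is solved by Cholesky-factorised normal equations per voxel;
  tests pin it (and the gradient regression) to an independent
  brute-force oracle at 1e-8 or better.
* Ordering conventions are deterministic everywhere a tie can occur:
  best maps and label votes break ties toward the lower condition value.
* Degenerate inputs — constant voxels, collinear fields, flat maps,
  single-label fields, non-positive means — are handled as explicit
  cases, not left to floating-point accident.
* Sessions are modelled singly; a combined multi-session model with
  per-session intercepts is out of scope, as are motion correction,
  slice timing and AR(1) prewhitening.

Measured end-to-end behaviour at the default settings (all recomputed by
the test suite and `scripts/acceptance.R`): the noiseless sparse chain
recovers the planted A1 frequency direction with a systematic bias of
about +7° — smoothing and the projection sphere mix signal across the
A1/R reversal border, rotating the fitted direction — while the rate
direction is nearly unbiased, so the recovered noiseless α is ≈ 118°
rather than exactly 112°. Across ten replicate noisy sessions the mean
recovered α is ≈ 120° (SD ≈ 11°), within the ±10° acceptance envelope
around the planted 112°, with every per-session fit keeping R² above
0.3. Noiseless phase mapping decodes 100 % of tuned voxels at every
tested haemodynamic delay, and the omnibus test's type-I rate on
pure-noise voxels is within 0.05 ± 0.02.

## Problem sizes

The shipped analyses run at desk scale by design: a 30 × 20 mm sheet
(651 vertices) in a 42 × 32 × 9 grid for the sparse experiments, a
16 × 12 mm sheet at 2 mm spacing for the phase experiment, single
sessions at the published volume counts (540/720/343), and ten replicate
sessions for the recovery analysis. These sizes keep every analysis
stage comfortably reproducible on one CPU while leaving all published
arithmetic (which has no size parameter) exact.

## Known limitations

* The flat-sheet idealisation means the principal-plane flattening step
  is exercised only in the exact-isometry regime; curved-surface
  distortion is untested by construction.
* Global scaling is per-volume (the convention under which the analysis
  was described); on synthetic grids dominated by responsive tissue it
  visibly offsets betas per condition, which the tests bound rather than
  remove.
* The phase-map correlation threshold is a convention; see above.
* The published per-hemisphere table contains two rows whose printed α
  is inconsistent with the printed directions (signs lost in printing);
  the package computes α from full signed directions and does not try to
  reproduce those two rows, only the aggregation arithmetic.
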