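#!/usr/bin/env Rscript
## Stage 4 -- phase-encoded tonotopy (continuous acquisition).
##
## Simulates one bidirectional pair of phase-encoded runs (TR 1.4 s,
## nine half-octave tones in 2 s blocks, 18 s progression + 12 s silence,
## 15 cycles), band-passes (0.02-0.1 Hz) and normalises to percent signal
## change, cross-correlates the two progressions, and decodes the lag
## into a preferred-frequency index per voxel and vertex. Reports the
## agreement with the planted tonotopy across haemodynamic delays.

library(audtopo)

dir.create("results", showWarnings = FALSE)
surf <- make_surface(sheet_spec(c(16, 12), 2, grid_margin_mm = 2, n_slices = 5))
truth <- make_ground_truth(surf$mesh, surf$parcellation)
pref <- audtopo:::voxel_tuning(surf$mesh, truth$freq_hz, 2)

rows <- list()
for (delay in c(0, 2, 4, 6)) {
  tm <- phase_timing(hemodynamic_delay_s = delay)
  A <- simulate_phase_runs(truth, surf$mesh, tm, "low_to_high",
                           noise_params(sd = 0, seed = 1))
  B <- simulate_phase_runs(truth, surf$mesh, tm, "high_to_low",
                           noise_params(sd = 0, seed = 2))
  pm <- phase_frequency_map(list(low_to_high = bandpass_psc(A),
                                 high_to_low = bandpass_psc(B)),
                            tm, surf$mesh)
  ktrue <- frequency_to_index(pref, tm)
  ok <- !is.na(ktrue)
  rows[[length(rows) + 1]] <- data.frame(
    hemodynamic_delay_s = delay,
    voxel_pct_correct = 100 * mean(pm$assignment$index[ok] == ktrue[ok]),
    vertex_pct_correct = 100 * mean(pm$vertex_index ==
                                      frequency_to_index(truth$freq_hz, tm)))
  message(sprintf("delay %d s: %.1f%% of voxels decode to the planted step",
                  delay, rows[[length(rows)]]$voxel_pct_correct))
}
write_table(do.call(rbind, rows), "results/phase_recovery.tsv")

## per-field preferred-frequency histogram at the default delay
tm <- phase_timing()
A <- simulate_phase_runs(truth, surf$mesh, tm, "low_to_high",
                         noise_params(sd = 0, seed = 1))
B <- simulate_phase_runs(truth, surf$mesh, tm, "high_to_low",
                         noise_params(sd = 0, seed = 2))
pm <- phase_frequency_map(list(low_to_high = bandpass_psc(A),
                               high_to_low = bandpass_psc(B)), tm, surf$mesh)
hist_rows <- list()
for (f in c("A1", "R", "RT")) {
  idx <- which(surf$parcellation == f)
  counts <- table(factor(pm$vertex_index[idx], levels = 0:8))
  hist_rows[[f]] <- data.frame(field = f, t(as.integer(counts)))
}
hist_tbl <- do.call(rbind, hist_rows)
names(hist_tbl)[-1] <- paste0("k", 0:8)
write_table(hist_tbl, "results/phase_field_histograms.tsv")
message("phase-mapping results in results/phase_recovery.tsv")
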