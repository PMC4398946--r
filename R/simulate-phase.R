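#' Timing of the phase-encoded acquisition
#'
#' Continuous EPI at TR 1.4 s while 9 pure-tone frequencies (half-octave
#' steps, 500-8000 Hz) are presented in 2 s blocks, forming an 18 s
#' progression followed by 12 s of silence; the 30 s cycle repeats 15 times
#' within a 343-volume run. Runs come in two types: low-to-high and
#' high-to-low progression order.
#'
#' @param TR_s repetition time (s).
#' @param tone_block_s duration of one frequency block (s).
#' @param n_frequencies number of frequency steps per progression.
#' @param silence_s silent pause after each progression (s).
#' @param n_cycles number of stimulus cycles per run.
#' @param n_volumes volumes per run.
#' @param hemodynamic_delay_s peak latency of the haemodynamic response (s).
#' @param base_frequency_hz lowest ladder frequency (Hz).
#' @return A list of class `phase_timing`; `frequencies_hz` holds the
#'   half-octave ladder, `progression_s` and `cycle_s` the derived timings.
#' @export
phase_timing <- function(TR_s = 1.4, tone_block_s = 2, n_frequencies = 9,
                         silence_s = 12, n_cycles = 15, n_volumes = 343,
                         hemodynamic_delay_s = 4, base_frequency_hz = 500) {
  progression_s <- n_frequencies * tone_block_s
  cycle_s <- progression_s + silence_s
  if (n_volumes * TR_s < n_cycles * cycle_s)
    stop("invalid timing: run shorter than the stimulus cycles")
  if (hemodynamic_delay_s < 0) stop("invalid timing: negative delay")
  structure(
    list(TR_s = TR_s, tone_block_s = tone_block_s,
         n_frequencies = as.integer(n_frequencies),
         progression_s = progression_s, silence_s = silence_s,
         cycle_s = cycle_s, n_cycles = as.integer(n_cycles),
         n_volumes = as.integer(n_volumes),
         hemodynamic_delay_s = hemodynamic_delay_s,
         frequencies_hz = base_frequency_hz * 2^(seq_len(n_frequencies) / 2 - 0.5)),
    class = "phase_timing")
}

# gamma-shaped HRF with unit peak at t = delay (shape delay+1, scale 1);
# delay 0 degenerates to an identity (no dispersion)
hrf_kernel <- function(delay_s, dt) {
  if (delay_s == 0) return(1)
  t <- seq(0, delay_s + 15, by = dt)
  h <- stats::dgamma(t, shape = delay_s + 1, scale = 1)
  h / max(h)
}

# within-cycle onset (s) of the block for frequency index k (0-based)
block_onset_s <- function(k, timing, direction) {
  k_eff <- if (direction == "low_to_high") k else (timing$n_frequencies - 1L - k)
  k_eff * timing$tone_block_s
}

#' Simulate one phase-encoded run
#'
#' Each voxel's neural response is a boxcar active during the 2 s block of
#' its preferred frequency in every cycle, convolved with a gamma-shaped
#' haemodynamic response peaking at `hemodynamic_delay_s`, sampled at the
#' TR, and scaled so the peak BOLD modulation equals the voxel's amplitude
#' (percent of baseline). The high-to-low run reverses the block order
#' within the progression only; cycle 1 starts at t = 0 and the trailing
#' part of the run is silence.
#'
#' @param truth,mesh planted maps and their mesh (see
#'   [simulate_sparse_experiment()]).
#' @param timing a [phase_timing()] object.
#' @param direction `"low_to_high"` or `"high_to_low"`.
#' @param noise a [noise_params()] object.
#' @param inherit_radius_mm voxel-to-vertex inheritance radius (mm).
#' @return A [volume_series()] with `TR_s = timing$TR_s`.
#' @export
simulate_phase_runs <- function(truth, mesh, timing = phase_timing(),
                                direction = c("low_to_high", "high_to_low"),
                                noise = noise_params(),
                                inherit_radius_mm = 2) {
  direction <- match.arg(direction)
  stopifnot(inherits(timing, "phase_timing"))

  pref <- voxel_tuning(mesh, truth$freq_hz, inherit_radius_mm)
  amp <- voxel_tuning(mesh, truth$amplitude_pct, inherit_radius_mm)
  kvox <- frequency_to_index(pref, timing)  # NA where baseline-only

  dt <- 0.1
  run_s <- timing$n_volumes * timing$TR_s
  tt <- seq(0, run_s, by = dt)
  kern <- hrf_kernel(timing$hemodynamic_delay_s, dt)
  vol_t <- (seq_len(timing$n_volumes) - 1L) * timing$TR_s
  vol_idx <- round(vol_t / dt) + 1L

  # one template per frequency index, sampled at the volume times
  templates <- matrix(0, timing$n_frequencies, timing$n_volumes)
  for (k in seq_len(timing$n_frequencies) - 1L) {
    onset <- block_onset_s(k, timing, direction)
    box <- numeric(length(tt))
    for (cyc in seq_len(timing$n_cycles) - 1L) {
      t0 <- cyc * timing$cycle_s + onset
      box[tt >= t0 & tt < t0 + timing$tone_block_s] <- 1
    }
    h <- if (length(kern) == 1) box else {
      full <- stats::convolve(box, rev(kern), type = "open")[seq_along(tt)]
      if (max(full) > 0) full / max(full) else full
    }
    templates[k + 1L, ] <- h[vol_idx]
  }

  n_vox <- length(pref)
  signal <- matrix(noise$baseline, n_vox, timing$n_volumes)
  active <- which(!is.na(kvox))
  signal[active, ] <- noise$baseline *
    (1 + (amp[active] / 100) * templates[kvox[active] + 1L, , drop = FALSE])
  signal <- signal + noise_matrix(noise, n_vox, timing$n_volumes)

  volume_series(array(signal, dim = c(mesh$grid$dim, timing$n_volumes)),
                voxel_mm = mesh$grid$voxel_mm,
                origin_mm = mesh$grid$origin_mm,
                TR_s = timing$TR_s, TA_s = timing$TR_s)
}
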