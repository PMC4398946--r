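#' Band-pass filter and percent-signal-change normalisation
#'
#' Zero-phase (forward-backward) Butterworth band-pass per voxel, removing
#' fluctuations below `low_hz` and above `high_hz`, followed by
#' normalisation to percent signal change relative to the voxel's pre-filter
#' mean: `100 * filtered / mean`. Output voxel means are approximately
#' zero. Voxels with non-positive mean are invalidated (all-NA).
#'
#' @param series a [volume_series()].
#' @param low_hz,high_hz pass-band edges (Hz); must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * TR)`.
#' @param order Butterworth section order (the zero-phase application
#'   squares the magnitude response).
#' @return The filtered series; component `valid` is a logical per-voxel
#'   vector.
#' @export
bandpass_psc <- function(series, low_hz = 0.02, high_hz = 0.1, order = 2) {
  stopifnot(inherits(series, "volume_series"))
  nyq <- 1 / (2 * series$TR_s)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  m <- as_voxel_matrix(series)
  means <- rowMeans(m)
  valid <- is.finite(means) & means > 0
  out <- matrix(NA_real_, nrow(m), ncol(m))
  # demean before filtering: the baseline offset is orders of magnitude
  # larger than the response and would otherwise dominate the forward and
  # backward pass as an edge transient
  for (i in which(valid))
    out[i, ] <- 100 * signal::filtfilt(bf, m[i, ] - means[i]) / means[i]
  res <- from_voxel_matrix(series, out)
  res$valid <- valid
  res
}

#' Cross-correlation lag between opposite-progression runs
#'
#' For every voxel, computes the correlation between the low-to-high and
#' high-to-low run time series as a function of circular time shift and
#' returns the lag maximising it, with parabolic sub-sample refinement
#' around the peak. Positive lag means the low-to-high response occurs
#' later in the cycle. The default method averages each run over its
#' stimulus cycles on a fine phase grid before correlating (equivalent for
#' periodic signals, and noise-reducing); `method = "full"` correlates the
#' full series circularly at TR resolution.
#'
#' @param pair list with components `low_to_high` and `high_to_low`
#'   ([volume_series()] objects preprocessed by [bandpass_psc()]) sharing
#'   one [phase_timing()].
#' @param timing the shared [phase_timing()].
#' @param method `"cycle"` (cycle-average first) or `"full"`.
#' @param phase_dt_s phase-grid resolution for the cycle method (s).
#' @return A list of class `lag_result`: per-voxel `lag_s` (within
#'   +/- cycle/2) and `peak_corr`.
#' @export
xcorr_lag <- function(pair, timing = phase_timing(),
                      method = c("cycle", "full"), phase_dt_s = 0.2) {
  method <- match.arg(method)
  A <- as_voxel_matrix(pair$low_to_high)
  B <- as_voxel_matrix(pair$high_to_low)
  if (!identical(dim(A), dim(B))) stop("runs must share grid and length")

  if (method == "cycle") {
    M <- cycle_average_matrix(timing, ncol(A), phase_dt_s)
    Az <- M %*% t(A)                        # phase x voxels
    Bz <- M %*% t(B)
    dt <- phase_dt_s
  } else {
    Az <- t(A)
    Bz <- t(B)
    dt <- timing$TR_s
  }
  np <- nrow(Az)
  # effectively flat profiles (zero variance up to rounding) are invalid
  flat_tol <- 1e-10 * pmax(1, apply(abs(Az), 2, max), apply(abs(Bz), 2, max))
  invalid <- apply(Az, 2, stats::sd) <= flat_tol |
    apply(Bz, 2, stats::sd) <= flat_tol
  Az <- scale(Az); Bz <- scale(Bz)
  Az[, invalid] <- NA_real_
  Bz[, invalid] <- NA_real_
  cors <- matrix(NA_real_, np, ncol(Az))
  for (L in 0:(np - 1)) {
    sh <- ((0:(np - 1) + L) %% np) + 1L
    cors[L + 1L, ] <- colSums(Az[sh, , drop = FALSE] * Bz) / (np - 1)
  }
  lag_s <- peak <- rep(NA_real_, ncol(Az))
  half <- timing$cycle_s / 2
  lag_grid <- (0:(np - 1)) * dt
  lag_grid[lag_grid > (np * dt) / 2] <- lag_grid[lag_grid > (np * dt) / 2] - np * dt
  in_range <- abs(lag_grid) <= half
  for (vx in seq_len(ncol(Az))) {
    cv <- cors[, vx]
    if (all(!is.finite(cv))) next
    cand <- which(in_range & is.finite(cv))
    i0 <- cand[which.max(cv[cand])]
    ip <- (i0 %% np) + 1L
    im <- ((i0 - 2) %% np) + 1L
    delta <- parabolic_offset(cv[im], cv[i0], cv[ip])
    lag_s[vx] <- lag_grid[i0] + delta * dt
    peak[vx] <- cv[i0]
  }
  structure(list(lag_s = lag_s, peak_corr = peak, method = method),
            class = "lag_result")
}

# vertex of the parabola through (-1, cm), (0, c0), (1, cp), clamped
parabolic_offset <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  d <- 0.5 * (cm - cp) / den
  max(min(d, 1), -1)
}

# phase-bin averaging operator: rows = phase-grid points over one cycle,
# columns = volumes; linear interpolation between volumes, averaged over
# the stimulus cycles
cycle_average_matrix <- function(timing, n_vol, phase_dt_s) {
  np <- round(timing$cycle_s / phase_dt_s)
  if (abs(np * phase_dt_s - timing$cycle_s) > 1e-9)
    stop("'phase_dt_s' must divide the cycle length")
  M <- matrix(0, np, n_vol)
  t_max <- (n_vol - 1) * timing$TR_s
  for (g in seq_len(np) - 1L) {
    for (cyc in seq_len(timing$n_cycles) - 1L) {
      t <- cyc * timing$cycle_s + g * phase_dt_s
      if (t > t_max) next
      i <- floor(t / timing$TR_s)
      w <- t / timing$TR_s - i
      M[g + 1L, i + 1L] <- M[g + 1L, i + 1L] + (1 - w)
      if (w > 0) M[g + 1L, i + 2L] <- M[g + 1L, i + 2L] + w
    }
    M[g + 1L, ] <- M[g + 1L, ] / sum(M[g + 1L, ])
  }
  M
}

#' Convert a cross-correlation lag to a preferred frequency
#'
#' Inverts the stimulus timing: a voxel preferring ladder step `k`
#' (0-based) responds `2 * k * block` seconds into the low-to-high
#' progression and `2 * (n - 1 - k) * block` seconds into the high-to-low
#' progression, so the inter-run lag is `2 * block * k - (n - 1) * block`,
#' i.e. `k = (lag + (n - 1) * block) / (2 * block)`. Because the measured
#' lag is circular within half a cycle while the admissible model lags span
#' slightly more than a cycle, the decoder assigns the ladder step whose
#' model lag is nearest to the measured lag modulo one cycle (so the
#' extreme steps, whose lags of +/-16 s alias to -/+14 s, are recovered
#' exactly). The haemodynamic delay is common to both runs and cancels.
#'
#' @param lag a [xcorr_lag()] result.
#' @param timing a [phase_timing()].
#' @param min_corr minimum peak correlation for a voxel to be assigned.
#' @return A list of class `frequency_assignment`: per-voxel `index`
#'   (0-based ladder step, NA if unassigned) and `frequency_hz`.
#' @export
lag_to_frequency <- function(lag, timing = phase_timing(), min_corr = 0.2) {
  stopifnot(inherits(lag, "lag_result"))
  nb <- timing$n_frequencies - 1L
  model_lags <- 2 * timing$tone_block_s * (0:nb) - nb * timing$tone_block_s
  # the measured lag is circular (within +/- cycle/2) while the admissible
  # model lags span (n-1) * 2 * block s, which can exceed the cycle: unwrap
  # by choosing the ladder step whose model lag is nearest to the lag or to
  # the lag shifted by one full cycle
  decode <- function(l) {
    if (!is.finite(l)) return(NA_integer_)
    cand <- c(l - timing$cycle_s, l, l + timing$cycle_s)
    d <- abs(outer(cand, model_lags, "-"))
    as.integer((which.min(apply(d, 2, min)) - 1L))
  }
  k <- vapply(lag$lag_s, decode, integer(1))
  bad <- !is.finite(lag$lag_s) | !is.finite(lag$peak_corr) |
    lag$peak_corr < min_corr
  k[bad] <- NA_integer_
  structure(
    list(index = as.integer(k),
         frequency_hz = timing$frequencies_hz[k + 1L]),
    class = "frequency_assignment")
}

#' Expected lag for a ladder step
#'
#' Forward direction of the timing model inverted by
#' [lag_to_frequency()]: the lag (s) between the low-to-high and
#' high-to-low responses of a voxel preferring step `k`.
#'
#' @param k 0-based ladder step.
#' @param timing a [phase_timing()].
#' @return Lag in seconds.
#' @export
frequency_to_lag <- function(k, timing = phase_timing()) {
  2 * timing$tone_block_s * k -
    (timing$n_frequencies - 1) * timing$tone_block_s
}

#' Preferred-frequency surface map from a phase-encoded run pair
#'
#' Full phase-encoded analysis for one pair of preprocessed runs:
#' cross-correlation lag per voxel, conversion to a preferred-frequency
#' ladder index, then projection onto the surface by majority vote within
#' the sampling sphere.
#'
#' @inheritParams xcorr_lag
#' @param mesh the `cortical_mesh` to project onto.
#' @param mask optional logical 3D array of voxels to include.
#' @param radius_mm projection sphere radius (mm).
#' @param min_corr minimum peak correlation for assignment.
#' @return A list: `vertex_index` (0-based ladder step per vertex),
#'   `vertex_frequency_hz`, plus the volumetric `assignment` and `lag`.
#' @export
phase_frequency_map <- function(pair, timing = phase_timing(), mesh,
                                mask = NULL, radius_mm = 1.6,
                                min_corr = 0.2, method = "cycle") {
  lag <- xcorr_lag(pair, timing, method = method)
  asg <- lag_to_frequency(lag, timing, min_corr)
  vol <- array(asg$index, dim = mesh$grid$dim)
  vi <- project_label(vol, mesh, radius_mm = radius_mm, mask = mask)
  list(vertex_index = as.integer(vi),
       vertex_frequency_hz = timing$frequencies_hz[as.integer(vi) + 1L],
       assignment = asg, lag = lag)
}
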