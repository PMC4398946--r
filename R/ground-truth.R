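#' Parameters of the planted topographic organisation
#'
#' The synthetic cortex carries two superimposed maps. Preferred
#' amplitude-modulation (AM) rate is organised in concentric iso-rate bands:
#' it is maximal (128 Hz) at a single centre and halves with every
#' `rate_decay_mm` of distance from it, clipped to `[0.5, 128]` Hz. The
#' highest tested stimulus rate, 512 Hz, is deliberately absent from the
#' planted map, reflecting that BOLD responses are barely tuned that high.
#' Preferred frequency is tonotopic: within each field, log2 preferred
#' frequency is an affine function of position along that field's axis, with
#' the axis direction reversing across the A1/R and R/RT borders.
#'
#' Angles are measured in the flattened-sheet frame: 0 deg = anterior,
#' 90 deg = lateral. The defaults place the A1 frequency-gradient direction
#' at 165 deg and the rate-gradient direction at 53 deg (so the planted
#' relative angle in A1 is 112 deg): the concentric centre is placed at
#' bearing `rate_centre_bearing_deg` from the A1 centroid at distance
#' `rate_centre_distance_mm`.
#'
#' @param rate_max_hz,rate_min_hz planted AM-rate range (Hz).
#' @param rate_decay_mm distance over which preferred rate halves (> 0).
#' @param rate_centre_bearing_deg bearing of the concentric centre from the
#'   A1 centroid (deg; 0 = anterior, 90 = lateral).
#' @param rate_centre_distance_mm distance of the centre from the A1
#'   centroid (mm).
#' @param freq_axis_deg named numeric: per-field tonotopic axis direction,
#'   the direction along which log2 preferred frequency increases.
#' @param freq_range_hz planted preferred-frequency range (Hz).
#' @param amplitude_pct peak BOLD response amplitude, percent signal change.
#' @param tuning_width_oct SD of the log2-Gaussian tuning curve, octaves.
#' @return A list of class `topo_params`.
#' @export
topo_params <- function(rate_max_hz = 128, rate_min_hz = 0.5,
                        rate_decay_mm = 3,
                        rate_centre_bearing_deg = 53,
                        rate_centre_distance_mm = 12,
                        freq_axis_deg = c(A1 = 165, R = 37, RT = 217,
                                          CL = 35, ML = 215, AL = 35,
                                          CM = 215, other = 345),
                        freq_range_hz = c(500, 16000),
                        amplitude_pct = 1, tuning_width_oct = 1.5) {
  if (!is.finite(rate_decay_mm) || rate_decay_mm <= 0)
    stop("invalid parameter: 'rate_decay_mm' must be > 0")
  if (rate_min_hz <= 0 || rate_max_hz <= rate_min_hz)
    stop("invalid parameter: rate range must satisfy 0 < min < max")
  if (any(freq_range_hz <= 0) || diff(freq_range_hz) <= 0)
    stop("invalid parameter: frequency range must satisfy 0 < min < max")
  structure(
    list(rate_max_hz = rate_max_hz, rate_min_hz = rate_min_hz,
         rate_decay_mm = rate_decay_mm,
         rate_centre_bearing_deg = rate_centre_bearing_deg,
         rate_centre_distance_mm = rate_centre_distance_mm,
         freq_axis_deg = freq_axis_deg, freq_range_hz = freq_range_hz,
         amplitude_pct = amplitude_pct, tuning_width_oct = tuning_width_oct),
    class = "topo_params")
}

#' Plant ground-truth rate and frequency maps on a cortical sheet
#'
#' @param mesh a `cortical_mesh` from [make_surface()].
#' @param parcellation matching `field_parcellation`.
#' @param params a [topo_params()] object.
#' @return A list of class `ground_truth` with per-vertex vectors
#'   `rate_hz`, `freq_hz`, `amplitude_pct`, `width_oct`, plus the rate
#'   `centre` (in anterior/lateral sheet coordinates) and the `params` used.
#' @examples
#' surf <- make_surface(sheet_spec())
#' truth <- make_ground_truth(surf$mesh, surf$parcellation)
#' range(truth$rate_hz)
#' @export
make_ground_truth <- function(mesh, parcellation, params = topo_params()) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  p <- if (inherits(params, "topo_params")) params else do.call(topo_params, params)
  uv <- sheet_coords(mesh)

  a1 <- field_vertices(parcellation, "A1")
  if (length(a1) == 0) stop("parcellation has no A1 vertices")
  a1_centroid <- colMeans(uv[a1, , drop = FALSE])
  theta <- p$rate_centre_bearing_deg * pi / 180
  centre <- a1_centroid + p$rate_centre_distance_mm * c(cos(theta), sin(theta))

  d <- sqrt((uv[, 1] - centre[1])^2 + (uv[, 2] - centre[2])^2)
  rate <- p$rate_max_hz * 2^(-d / p$rate_decay_mm)
  rate <- pmin(pmax(rate, p$rate_min_hz), p$rate_max_hz)

  lf_range <- log2(p$freq_range_hz)
  freq <- numeric(nrow(uv))
  for (f in levels(parcellation)) {
    idx <- field_vertices(parcellation, f)
    if (length(idx) == 0) next
    ax <- p$freq_axis_deg[[f]] * pi / 180
    sproj <- uv[idx, 1] * cos(ax) + uv[idx, 2] * sin(ax)
    span <- diff(range(sproj))
    if (span < .Machine$double.eps) {
      lf <- rep(mean(lf_range), length(idx))
    } else {
      lf <- mean(lf_range) +
        (sproj - mean(range(sproj))) * diff(lf_range) / span
    }
    freq[idx] <- 2^pmin(pmax(lf, lf_range[1]), lf_range[2])
  }

  structure(
    list(rate_hz = rate, freq_hz = freq,
         amplitude_pct = rep(p$amplitude_pct, nrow(uv)),
         width_oct = rep(p$tuning_width_oct, nrow(uv)),
         centre = centre, params = p),
    class = "ground_truth")
}

#' Log-Gaussian tuning curve
#'
#' Response fraction of a unit tuned to `preferred_hz` when driven at
#' `stimulus_hz`, Gaussian in log2 of the stimulus value with SD
#' `width_oct` octaves. Peak response is 1 at the preferred value.
#'
#' @param stimulus_hz,preferred_hz stimulus and preferred values (Hz).
#' @param width_oct tuning width in octaves.
#' @return Numeric response fraction in (0, 1].
#' @export
tuning_response <- function(stimulus_hz, preferred_hz, width_oct) {
  exp(-(log2(stimulus_hz) - log2(preferred_hz))^2 / (2 * width_oct^2))
}

#' Preferred-frequency index on the phase-encoded ladder
#'
#' Maps a preferred frequency in Hz to the nearest step of the half-octave
#' ladder used by the phase-encoded runs (index 0 = lowest frequency).
#'
#' @param freq_hz preferred frequency (Hz).
#' @param timing a [phase_timing()] object.
#' @return Integer index in `0:(n_frequencies - 1)`.
#' @export
frequency_to_index <- function(freq_hz, timing = phase_timing()) {
  k <- round(2 * log2(freq_hz / timing$frequencies_hz[1]))
  pmin(pmax(k, 0), timing$n_frequencies - 1L)
}
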