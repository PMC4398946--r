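#' Condition tables for the two sparse experiments
#'
#' The AM-rate experiment uses six modulation rates (0.5, 2, 8, 32, 128,
#' 512 Hz) on a broad-band noise carrier; the frequency experiment uses
#' three band-passed noise conditions whose bands are summarised here by
#' their geometric-centre frequencies (0.5-1, 2-4, 8-16 kHz).
#'
#' @return A data frame with columns `label`, `value_hz` and attribute
#'   `feature` (`"rate"` or `"frequency"`).
#' @export
rate_conditions <- function() {
  structure(
    data.frame(label = c("0.5", "2", "8", "32", "128", "512"),
               value_hz = c(0.5, 2, 8, 32, 128, 512),
               stringsAsFactors = FALSE),
    feature = "rate")
}

#' @rdname rate_conditions
#' @export
frequency_conditions <- function() {
  structure(
    data.frame(label = c("0.5-1k", "2-4k", "8-16k"),
               value_hz = c(sqrt(500 * 1000), sqrt(2000 * 4000),
                            sqrt(8000 * 16000)),
               stringsAsFactors = FALSE),
    feature = "frequency")
}

# preferred value per voxel, inherited from the nearest vertex within
# `radius_mm`; NA for voxels carrying baseline only
voxel_tuning <- function(mesh, values, radius_mm = 2) {
  g <- mesh$grid
  centres <- voxel_centres(g$dim, g$voxel_mm, g$origin_mm)
  nn <- nearest_vertex(centres, mesh$vertices)
  out <- values[nn$index]
  out[nn$dist > radius_mm] <- NA_real_
  out
}

# brute-force nearest vertex (small grids); returns index + distance
nearest_vertex <- function(points, vertices) {
  d2 <- matrix(0, nrow(points), nrow(vertices))
  for (c in 1:3)
    d2 <- d2 + outer(points[, c], vertices[, c], "-")^2
  idx <- max.col(-d2, ties.method = "first")
  list(index = idx, dist = sqrt(d2[cbind(seq_len(nrow(points)), idx)]))
}

#' Simulate a sparse-design BOLD experiment
#'
#' Generates one session of the sparse acquisition: at stimulus volumes the
#' voxel value is `baseline * (1 + a * G(condition) / 100)` where `G` is the
#' voxel's log2-Gaussian tuning curve evaluated at the condition value and
#' `a` the response amplitude in percent; baseline volumes carry no stimulus
#' term. Voxels inherit their tuning from the nearest mesh vertex within
#' `inherit_radius_mm`; more distant voxels are pure baseline. Additive
#' noise follows `noise`; identical seeds give identical series.
#'
#' @param truth a `ground_truth` object.
#' @param mesh the `cortical_mesh` the truth lives on.
#' @param schedule a [make_schedule()] result.
#' @param conditions condition table ([rate_conditions()] or
#'   [frequency_conditions()]); labels must match the schedule's.
#' @param noise a [noise_params()] object.
#' @param inherit_radius_mm voxel-to-vertex inheritance radius (mm).
#' @return A [volume_series()] on the mesh's grid.
#' @export
simulate_sparse_experiment <- function(truth, mesh, schedule, conditions,
                                       noise = noise_params(),
                                       inherit_radius_mm = 2) {
  stopifnot(inherits(truth, "ground_truth"), inherits(mesh, "cortical_mesh"))
  feature <- attr(conditions, "feature")
  if (is.null(feature) || !feature %in% c("rate", "frequency"))
    stop("'conditions' must carry a 'feature' attribute (rate or frequency)")
  if (!setequal(schedule_conditions(schedule), conditions$label))
    stop("schedule and condition labels disagree")

  pref_all <- if (feature == "rate") truth$rate_hz else truth$freq_hz
  # stimulus domain of the experiment, not of the (clipped) planted map
  domain <- if (feature == "rate") c(0.5, 512) else c(500, 16000)
  pref <- voxel_tuning(mesh, pref_all, inherit_radius_mm)
  amp <- voxel_tuning(mesh, truth$amplitude_pct, inherit_radius_mm)
  width <- voxel_tuning(mesh, truth$width_oct, inherit_radius_mm)

  # per-voxel response fraction for each condition (0 where baseline-only)
  resp <- matrix(0, length(pref), nrow(conditions))
  active <- !is.na(pref)
  for (c in seq_len(nrow(conditions))) {
    v <- conditions$value_hz[c]
    if (v < domain[1] || v > domain[2]) {
      warning(sprintf("condition %s (%g Hz) outside simulated tuning domain; zero response",
                      conditions$label[c], v))
      next
    }
    resp[active, c] <- amp[active] *
      tuning_response(v, pref[active], width[active])
  }

  n_t <- nrow(schedule)
  stim <- match(schedule$condition, conditions$label)  # NA at baseline
  signal <- matrix(noise$baseline, length(pref), n_t)
  on <- which(!is.na(stim))
  signal[, on] <- noise$baseline *
    (1 + resp[, stim[on], drop = FALSE] / 100)
  signal <- signal + noise_matrix(noise, length(pref), n_t)

  volume_series(array(signal, dim = c(mesh$grid$dim, n_t)),
                voxel_mm = mesh$grid$voxel_mm,
                origin_mm = mesh$grid$origin_mm,
                TR_s = attr(schedule, "TR_s"), TA_s = attr(schedule, "TA_s"))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
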