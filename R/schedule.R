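#' Build a sparse-design stimulus schedule
#'
#' Sparse temporal sampling alternates stimulus and silent-baseline volumes:
#' every other volume is acquired without a preceding stimulus. Stimulus
#' volumes are balanced across conditions and ordered pseudo-randomly under
#' the given seed. With 540 volumes and six AM-rate conditions this yields
#' 45 volumes per condition and 270 baseline volumes; with 720 volumes and
#' three frequency-band conditions, 120 per condition.
#'
#' @param n_volumes total number of volumes (even).
#' @param condition_labels character vector of condition names.
#' @param seed integer seed for the condition order.
#' @param TR_s,TA_s repetition and acquisition time in seconds.
#' @return A data frame of class `stimulus_schedule` with columns
#'   `volume` (0-based index) and `condition` (`"baseline"` or a condition
#'   label); attributes `TR_s`, `TA_s`, `conditions`.
#' @examples
#' sched <- make_schedule(540, c("0.5", "2", "8", "32", "128", "512"), seed = 1)
#' table(sched$condition)
#' @export
make_schedule <- function(n_volumes, condition_labels, seed = 1,
                          TR_s = 10, TA_s = 1) {
  n_volumes <- as.integer(n_volumes)
  condition_labels <- as.character(condition_labels)
  if (n_volumes < 2L || n_volumes %% 2L != 0L)
    stop("invalid schedule: 'n_volumes' must be even and >= 2")
  if (anyDuplicated(condition_labels) || length(condition_labels) == 0)
    stop("invalid schedule: condition labels must be unique and non-empty")
  if ("baseline" %in% condition_labels)
    stop("invalid schedule: 'baseline' is reserved")
  n_stim <- n_volumes %/% 2L
  k <- length(condition_labels)
  if (n_stim %% k != 0L)
    stop(sprintf(
      "invalid schedule: %d stimulus volumes cannot be balanced across %d conditions",
      n_stim, k))
  reps <- n_stim %/% k
  order <- with_seed(seed, sample(rep(condition_labels, each = reps)))
  condition <- rep("baseline", n_volumes)
  condition[seq(2L, n_volumes, by = 2L)] <- order  # volume 0 is baseline
  structure(
    data.frame(volume = seq_len(n_volumes) - 1L, condition = condition,
               stringsAsFactors = FALSE),
    TR_s = TR_s, TA_s = TA_s, conditions = condition_labels,
    class = c("stimulus_schedule", "data.frame"))
}

schedule_conditions <- function(schedule) attr(schedule, "conditions")

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Noise model for the BOLD simulators
#'
#' Additive Gaussian noise around a constant baseline, optionally with lag-1
#' autocorrelation. Identical seeds yield identical simulated series.
#'
#' @param baseline baseline signal level (arbitrary units; the GLM's global
#'   scaling maps it to 100).
#' @param sd Gaussian noise SD, same units as `baseline` (>= 0).
#' @param ar1 lag-1 autocorrelation coefficient in `[0, 1)`.
#' @param seed integer seed.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(baseline = 100, sd = 0, ar1 = 0, seed = 1) {
  if (!is.finite(sd) || sd < 0) stop("noise 'sd' must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("'ar1' must be in [0, 1)")
  structure(list(baseline = baseline, sd = sd, ar1 = ar1, seed = seed),
            class = "noise_params")
}

# (voxels x time) noise matrix; AR(1) applied along time, stationary scaling
noise_matrix <- function(noise, n_vox, n_t) {
  if (noise$sd == 0) return(matrix(0, n_vox, n_t))
  with_seed(noise$seed, {
    eps <- matrix(rnorm(n_vox * n_t, sd = noise$sd), n_vox, n_t)
    if (noise$ar1 > 0) {
      innov_sd <- sqrt(1 - noise$ar1^2)
      out <- eps
      out[, 1] <- eps[, 1]
      for (t in 2:n_t) out[, t] <- noise$ar1 * out[, t - 1] + innov_sd * eps[, t]
      out
    } else eps
  })
}
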