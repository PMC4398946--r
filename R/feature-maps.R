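#' Contrast map between high and low stimulus sets
#'
#' Voxel-wise difference `mean(beta over high_set) - mean(beta over
#' low_set)`, the degree of preference for high over low stimulus values.
#' The AM-rate analysis contrasts the two highest rates (128, 512 Hz)
#' against the two lowest (0.5, 2 Hz), ignoring the intermediate rates; the
#' frequency analysis contrasts the 8-16 kHz band against the 0.5-1 kHz
#' band. The sign convention (high minus low) is recorded in the result's
#' provenance so plots can flip it without ambiguity.
#'
#' @param statmaps a [fit_glm()] result.
#' @param low_set,high_set disjoint character vectors of condition labels.
#' @param mask logical 3D array (e.g. from [omnibus_mask()]); the contrast
#'   is `NA` outside it.
#' @return Numeric 3D array of class `contrast_map` with attribute
#'   `provenance` (list with `low`, `high`, `sign = "high-low"`).
#' @examples
#' # betas 1..6 over the six rates: mean(5,7) - mean(1,2) = 4.5 for
#' # high = {128, 512}, low = {0.5, 2}
#' @export
contrast_map <- function(statmaps, low_set, high_set, mask = NULL) {
  stopifnot(inherits(statmaps, "stat_maps"))
  low_set <- as.character(low_set); high_set <- as.character(high_set)
  if (length(low_set) == 0 || length(high_set) == 0)
    stop("low and high sets must be non-empty")
  if (length(intersect(low_set, high_set)) > 0)
    stop("low and high sets overlap")
  missing <- setdiff(c(low_set, high_set), statmaps$conditions)
  if (length(missing) > 0)
    stop("unknown conditions: ", paste(missing, collapse = ", "))
  li <- match(low_set, statmaps$conditions)
  hi <- match(high_set, statmaps$conditions)
  val <- rowMeans(statmaps$beta[, hi, drop = FALSE]) -
    rowMeans(statmaps$beta[, li, drop = FALSE])
  if (!is.null(mask)) val[!as.logical(mask)] <- NA_real_
  structure(array(val, dim = statmaps$dim),
            provenance = list(low = low_set, high = high_set,
                              sign = "high-low"),
            class = c("contrast_map", "array"))
}

#' Best-condition (best rate / best frequency) map
#'
#' Identifies, voxel by voxel, which condition shows the highest t-value.
#' Exact ties are broken toward the lower condition value; voxels where no
#' finite winner exists are flagged missing (NA).
#'
#' @param statmaps a [fit_glm()] result.
#' @param condition_values numeric stimulus value for each condition (used
#'   to order ties); defaults to parsing the labels where possible.
#' @param mask logical 3D array; the map is `NA` outside it.
#' @return Integer 3D array of class `best_map` holding 1-based indices
#'   into the value-ordered condition ladder; attributes `labels` and
#'   `values_hz` give the ladder.
#' @export
best_map <- function(statmaps, condition_values = NULL, mask = NULL) {
  stopifnot(inherits(statmaps, "stat_maps"))
  k <- length(statmaps$conditions)
  if (is.null(condition_values))
    condition_values <- suppressWarnings(as.numeric(statmaps$conditions))
  if (any(!is.finite(condition_values)) || length(condition_values) != k)
    stop("'condition_values' must give a finite value per condition")
  ord <- order(condition_values)
  tmat <- statmaps$t[, ord, drop = FALSE]
  ok <- rowSums(is.finite(tmat)) > 0
  tmat[!is.finite(tmat)] <- -Inf
  win <- max.col(tmat, ties.method = "first")  # first = lower value wins ties
  win[!ok] <- NA_integer_
  if (!is.null(mask)) win[!as.logical(mask)] <- NA_integer_
  structure(array(as.integer(win), dim = statmaps$dim),
            labels = statmaps$conditions[ord],
            values_hz = condition_values[ord],
            class = c("best_map", "array"))
}
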