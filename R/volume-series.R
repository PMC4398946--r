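#' 4D BOLD volume series
#'
#' Container for a simulated (or loaded) BOLD acquisition: a 4D scalar grid
#' in `(x, y, z, t)` order with voxel sizes in mm and acquisition timing.
#' World coordinates are mm, right-handed, with +x anterior; voxel indexing
#' is 0-based and the centre of voxel `(i, j, k)` lies at
#' `origin_mm + (c(i, j, k) + 0.5) * voxel_mm`.
#'
#' @param data numeric 4D array, dimensions `(nx, ny, nz, nt)`.
#' @param voxel_mm numeric length-3, voxel size in mm (all > 0).
#' @param origin_mm numeric length-3, world coordinate of the grid corner.
#' @param TR_s repetition time in seconds (volume-to-volume spacing).
#' @param TA_s volume acquisition time in seconds (`TA_s <= TR_s`).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_mm, origin_mm = c(0, 0, 0),
                          TR_s = 10, TA_s = 1) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t)")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("'voxel_mm' must be three positive values")
  if (TA_s > TR_s) stop("'TA_s' cannot exceed 'TR_s'")
  structure(
    list(data = data, voxel_mm = voxel_mm, origin_mm = as.numeric(origin_mm),
         TR_s = TR_s, TA_s = TA_s),
    class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size %s mm, TR %.3g s, TA %.3g s\n",
              paste(format(x$voxel_mm), collapse = " x "), x$TR_s, x$TA_s))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

n_volumes <- function(series) dim(series$data)[4]
n_voxels <- function(series) prod(dim(series$data)[1:3])

# series data as (voxels x time) matrix
as_voxel_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
}

# replace the data of a series from a (voxels x time) matrix
from_voxel_matrix <- function(series, mat) {
  series$data <- array(mat, dim = dim(series$data))
  series
}

# world coordinates (n x 3) of all voxel centres, x fastest
voxel_centres <- function(dim3, voxel_mm, origin_mm) {
  idx <- as.matrix(expand.grid(i = seq_len(dim3[1]) - 1L,
                               j = seq_len(dim3[2]) - 1L,
                               k = seq_len(dim3[3]) - 1L))
  sweep(sweep(idx + 0.5, 2, voxel_mm, "*"), 2, origin_mm, "+")
}
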