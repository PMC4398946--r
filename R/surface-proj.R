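#' Project a voxel map onto surface vertices
#'
#' For each vertex, averages the values of in-mask voxels whose centres lie
#' within `radius_mm` of the vertex (the classic "data in a sphere"
#' projection). Vertices with no qualifying voxel are missing (NA).
#' Membership is decided by voxel-centre distance, not partial-volume
#' weighting, and the projection is mask-restricted so baseline-only voxels
#' never dilute vertex values.
#'
#' @param volume 3D numeric array in the mesh's grid frame (e.g. a
#'   [contrast_map()]).
#' @param mesh a `cortical_mesh`.
#' @param radius_mm sampling sphere radius in mm (> 0).
#' @param mask optional logical 3D array restricting the contributing
#'   voxels (NA voxels are always excluded).
#' @return Numeric per-vertex values (length = vertex count) with attribute
#'   `radius_mm`.
#' @export
project_scalar <- function(volume, mesh, radius_mm = 1.6, mask = NULL) {
  nb <- sphere_neighbours(volume, mesh, radius_mm, mask)
  out <- vapply(seq_len(nrow(mesh$vertices)), function(v) {
    vox <- nb$values[nb$neighbours[[v]]]
    if (length(vox) == 0) NA_real_ else mean(vox)
  }, numeric(1))
  structure(out, radius_mm = radius_mm)
}

#' Project a label volume onto surface vertices by majority vote
#'
#' As [project_scalar()], but for label volumes (e.g. a [best_map()]):
#' each vertex takes the majority label among the enclosed in-mask voxels,
#' with ties broken toward the lower label (lower condition value, given
#' value-ordered integer labels).
#'
#' @inheritParams project_scalar
#' @param volume 3D integer label array; labels must be ordered by
#'   condition value for the tie rule to be meaningful.
#' @return Integer per-vertex labels with NA where no voxel qualifies.
#' @export
project_label <- function(volume, mesh, radius_mm = 1.6, mask = NULL) {
  nb <- sphere_neighbours(volume, mesh, radius_mm, mask)
  out <- vapply(seq_len(nrow(mesh$vertices)), function(v) {
    vox <- nb$values[nb$neighbours[[v]]]
    vox <- vox[!is.na(vox)]
    if (length(vox) == 0) return(NA_integer_)
    counts <- table(vox)
    lab <- as.integer(names(counts))
    # ties toward the lower label value
    lab[order(-as.integer(counts), lab)][1]
  }, integer(1))
  structure(out, radius_mm = radius_mm)
}

# shared machinery: per-vertex indices of candidate voxels within radius
sphere_neighbours <- function(volume, mesh, radius_mm, mask) {
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("'radius_mm' must be > 0")
  g <- mesh$grid
  if (!identical(dim(volume), as.integer(g$dim)) &&
      !identical(dim(volume), g$dim))
    stop("volume dimensions do not match the mesh grid")
  vals <- as.vector(volume)
  keep <- !is.na(vals)
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  centres <- voxel_centres(g$dim, g$voxel_mm, g$origin_mm)[keep, , drop = FALSE]
  idx_keep <- which(keep)
  verts <- mesh$vertices
  neighbours <- vector("list", nrow(verts))
  if (length(idx_keep) > 0) {
    r2 <- radius_mm^2
    for (v in seq_len(nrow(verts))) {
      d2 <- (centres[, 1] - verts[v, 1])^2 +
        (centres[, 2] - verts[v, 2])^2 +
        (centres[, 3] - verts[v, 3])^2
      neighbours[[v]] <- idx_keep[d2 <= r2]
    }
  }
  list(neighbours = neighbours, values = vals)
}
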