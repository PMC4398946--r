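#' Specification of a synthetic cortical sheet
#'
#' Describes a flat rectangular stand-in for the superior temporal plane: its
#' extent, triangulation density, hemisphere, and the enclosing 3D voxel grid
#' used by the BOLD simulators. The sheet lies in the `z = 0` plane at the
#' axial centre of the grid. For a left hemisphere the lateral direction is
#' +y; right-hemisphere sheets are generated as mirror images (lateral = -y).
#'
#' @param extent_mm length-2 numeric, (width, height) of the sheet in mm;
#'   width runs along the anterior axis, height along the lateral axis.
#' @param vertex_spacing_mm triangulation spacing in mm (> 0).
#' @param hemisphere `"left"` or `"right"`.
#' @param voxel_mm length-3 voxel size in mm of the enclosing grid.
#' @param grid_margin_mm in-plane margin of the grid around the sheet, mm.
#' @param n_slices number of axial slices in the grid.
#' @return An object of class `sheet_spec`.
#' @examples
#' spec <- sheet_spec(c(20, 30), 1)
#' @export
sheet_spec <- function(extent_mm = c(30, 20), vertex_spacing_mm = 1,
                       hemisphere = c("left", "right"),
                       voxel_mm = c(1, 1, 1), grid_margin_mm = 6,
                       n_slices = 9) {
  hemisphere <- match.arg(hemisphere)
  extent_mm <- as.numeric(extent_mm)
  if (length(extent_mm) != 2L || any(!is.finite(extent_mm)) || any(extent_mm <= 0))
    stop("invalid sheet spec: 'extent_mm' must be two positive values")
  if (!is.finite(vertex_spacing_mm) || vertex_spacing_mm <= 0)
    stop("invalid sheet spec: 'vertex_spacing_mm' must be > 0")
  n_side <- extent_mm / vertex_spacing_mm
  if (max(abs(n_side - round(n_side))) > 1e-8)
    stop("invalid sheet spec: spacing must divide both extents")
  if (any(round(n_side) + 1 < 3))
    stop("invalid sheet spec: fewer than 3 vertices per side")
  if (any(voxel_mm <= 0)) stop("invalid sheet spec: voxel size must be > 0")
  structure(
    list(extent_mm = extent_mm, vertex_spacing_mm = vertex_spacing_mm,
         hemisphere = hemisphere, voxel_mm = as.numeric(voxel_mm),
         grid_margin_mm = grid_margin_mm, n_slices = as.integer(n_slices)),
    class = "sheet_spec")
}

#' Auditory field labels used by the parcellation
#'
#' Core fields (A1, R, RT) and the surrounding belt fields (CL, ML, AL, CM)
#' of the primate superior temporal plane, plus a catch-all `other`.
#' @return Character vector of field labels.
#' @export
field_levels <- function() c("A1", "R", "RT", "CL", "ML", "AL", "CM", "other")

#' Generate a triangulated cortical sheet with its field parcellation
#'
#' Builds a regular planar triangle mesh embedded in the 3D voxel grid of the
#' spec, and labels every vertex with an auditory field. The layout follows
#' the standard mosaic of the macaque superior temporal plane: the core
#' fields A1, R and RT form a posterior-to-anterior band at mid
#' mediolateral position, the belt fields CL, ML and AL form a lateral strip
#' (posterior to anterior), and CM sits postero-medially.
#'
#' @param spec a [sheet_spec()].
#' @return A list with components `mesh` (class `cortical_mesh`: `vertices`
#'   n x 3 mm coordinates, `triangles` m x 3 vertex indices, `hemisphere`,
#'   anatomical `axes`, and the enclosing `grid`) and `parcellation` (factor
#'   of per-vertex field labels, class `field_parcellation`).
#' @examples
#' surf <- make_surface(sheet_spec(c(20, 30), 1))
#' nrow(surf$mesh$vertices)  # 21 * 31
#' @export
make_surface <- function(spec) {
  stopifnot(inherits(spec, "sheet_spec"))
  w <- spec$extent_mm[1]; h <- spec$extent_mm[2]; s <- spec$vertex_spacing_mm
  nx <- as.integer(round(w / s)) + 1L
  ny <- as.integer(round(h / s)) + 1L

  xs <- seq(0, w, length.out = nx)          # anterior coordinate
  ls <- seq(0, h, length.out = ny)          # lateral coordinate (unsigned)
  grid <- expand.grid(x = xs, l = ls)       # x fastest
  mirror <- if (spec$hemisphere == "right") -1 else 1
  vertices <- cbind(grid$x, mirror * grid$l, 0)

  # two triangles per grid cell
  cell <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L))
  v1 <- (cell$j - 1L) * nx + cell$i
  v2 <- v1 + 1L
  v3 <- v1 + nx
  v4 <- v3 + 1L
  triangles <- rbind(cbind(v1, v2, v3), cbind(v2, v4, v3))
  dimnames(triangles) <- NULL

  margin <- spec$grid_margin_mm
  nvx <- ceiling((w + 2 * margin) / spec$voxel_mm[1])
  nvy <- ceiling((h + 2 * margin) / spec$voxel_mm[2])
  nvz <- spec$n_slices
  oy <- if (spec$hemisphere == "right") -(h + margin) else -margin
  origin <- c(-margin, oy, -nvz * spec$voxel_mm[3] / 2)

  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         hemisphere = spec$hemisphere,
         axes = list(anterior = c(1, 0, 0), lateral = c(0, mirror, 0)),
         grid = list(dim = c(nvx, nvy, nvz), voxel_mm = spec$voxel_mm,
                     origin_mm = origin),
         spacing_mm = s, extent_mm = spec$extent_mm),
    class = "cortical_mesh")

  parcellation <- parcellate_sheet(grid$x / w, grid$l / h)
  list(mesh = mesh, parcellation = parcellation)
}

# Field mosaic in fractional sheet coordinates: fx anterior fraction
# (0 = posterior edge), fl lateral fraction (0 = medial edge).
parcellate_sheet <- function(fx, fl) {
  lab <- rep("other", length(fx))
  core <- fl >= 0.25 & fl < 0.6
  lab[core & fx < 0.45] <- "A1"
  lab[core & fx >= 0.45 & fx < 0.75] <- "R"
  lab[core & fx >= 0.75] <- "RT"
  lat <- fl >= 0.6
  lab[lat & fx < 0.35] <- "CL"
  lab[lat & fx >= 0.35 & fx < 0.7] <- "ML"
  lab[lat & fx >= 0.7] <- "AL"
  lab[fl < 0.25 & fx < 0.5] <- "CM"
  structure(factor(lab, levels = field_levels()), class = c("field_parcellation", "factor"))
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %d vertices, %d triangles (%s hemisphere)\n",
              nrow(x$vertices), nrow(x$triangles), x$hemisphere))
  invisible(x)
}

# lateral (unsigned) coordinate of mesh vertices or arbitrary points
lateral_coord <- function(mesh, points = mesh$vertices) {
  as.numeric(points %*% mesh$axes$lateral)
}

anterior_coord <- function(mesh, points = mesh$vertices) {
  as.numeric(points %*% mesh$axes$anterior)
}

# per-vertex (anterior, lateral) sheet coordinates
sheet_coords <- function(mesh) {
  cbind(u = anterior_coord(mesh), l = lateral_coord(mesh))
}

field_vertices <- function(parcellation, field) {
  which(as.character(parcellation) == field)
}
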