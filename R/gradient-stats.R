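#' Flatten one auditory field to 2D coordinates
#'
#' Projects the field's vertices onto their best-fit plane (principal-axes
#' projection) and expresses them in a common anatomical frame: +u =
#' anterior, +v = lateral. Because the lateral axis of a right-hemisphere
#' mesh points in the mirrored direction, the resulting coordinates are
#' automatically comparable across hemispheres (0 deg = anterior, 90 deg =
#' lateral, in both).
#'
#' @param mesh a `cortical_mesh`.
#' @param parcellation matching `field_parcellation`.
#' @param field field label (e.g. `"A1"`).
#' @return A data frame of class `flat_coords` with columns `vertex`
#'   (index into the mesh), `u`, `v` (mm).
#' @export
flatten_field <- function(mesh, parcellation, field) {
  idx <- field_vertices(parcellation, field)
  if (length(idx) < 4) stop(sprintf("field %s has fewer than 4 vertices", field))
  X <- mesh$vertices[idx, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1))
    stop(sprintf("field %s is degenerate (collinear vertices)", field))
  normal <- ev$vectors[, 3]

  e1 <- mesh$axes$anterior - sum(mesh$axes$anterior * normal) * normal
  if (sqrt(sum(e1^2)) < 1e-9)
    stop("anterior axis is perpendicular to the field plane")
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- mesh$axes$lateral - sum(mesh$axes$lateral * normal) * normal -
    sum(mesh$axes$lateral * e1) * e1
  if (sqrt(sum(e2^2)) < 1e-9)
    stop("lateral axis is degenerate in the field plane")
  e2 <- e2 / sqrt(sum(e2^2))

  structure(
    data.frame(vertex = idx, u = as.numeric(Xc %*% e1),
               v = as.numeric(Xc %*% e2)),
    field = field, hemisphere = mesh$hemisphere,
    class = c("flat_coords", "data.frame"))
}

#' 2D regression gradient of a surface map within a field
#'
#' Least-squares fit `value = b0 + bu * u + bv * v` over the field's
#' vertices. The gradient direction is `atan2(bv, bu)` in degrees in
#' `[0, 360)` (0 = anterior, 90 = lateral); its magnitude is
#' `sqrt(bu^2 + bv^2)` in map units per mm. Significance is the F test of
#' `(bu, bv)` jointly zero on (2, n - 3) degrees of freedom.
#'
#' @param coords a [flatten_field()] result.
#' @param values per-vertex map values (full-mesh vector, indexed by
#'   `coords$vertex`, or a vector of `nrow(coords)` values).
#' @return A list of class `gradient_fit`: `direction_deg`, `magnitude`,
#'   `r_squared`, `p_value`, `n`, `coef`.
#' @export
fit_gradient <- function(coords, values) {
  stopifnot(inherits(coords, "flat_coords"))
  vals <- if (length(values) == nrow(coords)) values else values[coords$vertex]
  ok <- is.finite(vals)
  n <- sum(ok)
  if (n < 4) stop("fewer than 4 non-missing vertices")
  u <- coords$u[ok]; v <- coords$v[ok]; y <- vals[ok]
  X <- cbind(1, u, v)
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  magnitude <- sqrt(b[2]^2 + b[3]^2)
  # degenerate-fit guard scaled to the data (constant maps have sd 0 but
  # may leave ~1e-17 coefficients behind)
  tol <- 1e-10 * max(stats::sd(y), 1e-6 * abs(mean(y)), .Machine$double.eps)
  if (!is.finite(magnitude) || magnitude <= tol) {
    direction <- NA_real_
    r2 <- 0
    p <- 1
  } else {
    direction <- (atan2(b[3], b[2]) * 180 / pi) %% 360
    Fstat <- (r2 / 2) / ((1 - r2) / (n - 3))
    p <- stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
    if (tss > 0 && rss <= 1e-14 * tss) p <- 0
  }
  structure(
    list(direction_deg = unname(direction), magnitude = unname(magnitude),
         r_squared = unname(r2), p_value = unname(p), n = n,
         coef = unname(b)),
    class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient_fit> direction %.1f deg, R^2 %.2f, p %s, n %d\n",
              x$direction_deg, x$r_squared, format_p(x$p_value), x$n))
  invisible(x)
}

#' Relative angle between two gradient directions
#'
#' The unsigned angle between two full directions, in `[0, 180]`:
#' `min(|d1 - d2| mod 360, 360 - |d1 - d2| mod 360)`. Symmetric in its
#' arguments; NA if either direction is missing.
#'
#' @param dir1_deg,dir2_deg directions in degrees.
#' @return Relative angle in degrees.
#' @examples
#' relative_angle(162, 25)  # 137
#' relative_angle(10, 350)  # 20
#' @export
relative_angle <- function(dir1_deg, dir2_deg) {
  out <- abs(dir1_deg - dir2_deg) %% 360
  pmin(out, 360 - out)
}

#' Gradient analysis of a best-condition map
#'
#' Applies the same 2D regression to the ordinal condition indices of a
#' best-rate or best-frequency map projected on the surface. Fields whose
#' vertices all share a single best condition carry no gradient and raise
#' an error.
#'
#' @param coords a [flatten_field()] result.
#' @param labels per-vertex integer condition indices (value-ordered).
#' @return A `gradient_fit` with attribute `ordinal = TRUE`.
#' @export
best_map_gradient <- function(coords, labels) {
  vals <- if (length(labels) == nrow(coords)) labels else labels[coords$vertex]
  uniq <- unique(vals[is.finite(vals)])
  if (length(uniq) < 2)
    stop("no gradient can be specified: field has a single best condition")
  fit <- fit_gradient(coords, as.numeric(vals))
  attr(fit, "ordinal") <- TRUE
  fit
}

#' Mean and sample SD of table rows
#'
#' The aggregation used for the per-field Average / Std-dev rows: plain
#' arithmetic mean and sample standard deviation (n - 1 denominator);
#' with a single row the SD is reported missing.
#'
#' @param x numeric vector of per-hemisphere values.
#' @return A list with `average` and `std_dev`.
#' @export
summarize_field_stats <- function(x) {
  x <- x[is.finite(x)]
  list(average = mean(x),
       std_dev = if (length(x) > 1) stats::sd(x) else NA_real_)
}

#' Per-field gradient and relative-angle summary table
#'
#' Runs the full gradient analysis for every dataset (animal x hemisphere)
#' and field: flatten the field, fit the frequency- and rate-contrast
#' gradients, and compute the relative angle between them. Per-field
#' Average and Std-dev rows (plain means, sample SD) are appended.
#'
#' @param datasets a list; each element is a list with components `animal`,
#'   `hemisphere`, `mesh`, `parcellation`, `rate_values`, `freq_values`
#'   (per-vertex projected contrast values).
#' @param fields fields to analyse.
#' @return A data frame of class `gradient_table` with columns `animal`,
#'   `hemisphere`, `field`, `alpha_deg`, `freq_dir_deg`, `freq_r2`,
#'   `freq_p`, `rate_dir_deg`, `rate_r2`, `rate_p`, `n_vertices`.
#' @export
field_gradient_table <- function(datasets, fields = c("A1", "R", "CL")) {
  rows <- list()
  for (field in fields) {
    member <- list()
    for (ds in datasets) {
      coords <- tryCatch(
        flatten_field(ds$mesh, ds$parcellation, field),
        error = function(e) {
          warning(sprintf("skipping %s %s/%s: %s", field, ds$animal,
                          ds$hemisphere, conditionMessage(e)))
          NULL
        })
      if (is.null(coords)) next
      ff <- fit_gradient(coords, ds$freq_values)
      rf <- fit_gradient(coords, ds$rate_values)
      member[[length(member) + 1L]] <- data.frame(
        animal = ds$animal, hemisphere = ds$hemisphere, field = field,
        alpha_deg = relative_angle(ff$direction_deg, rf$direction_deg),
        freq_dir_deg = ff$direction_deg, freq_r2 = ff$r_squared,
        freq_p = ff$p_value,
        rate_dir_deg = rf$direction_deg, rate_r2 = rf$r_squared,
        rate_p = rf$p_value, n_vertices = ff$n,
        stringsAsFactors = FALSE)
    }
    if (length(member) == 0) next
    block <- do.call(rbind, member)
    num_cols <- c("alpha_deg", "freq_dir_deg", "freq_r2",
                  "rate_dir_deg", "rate_r2", "n_vertices")
    avg <- sdv <- block[1, ]
    avg$animal <- "Average"; sdv$animal <- "Std dev"
    avg$hemisphere <- sdv$hemisphere <- ""
    avg$freq_p <- sdv$freq_p <- avg$rate_p <- sdv$rate_p <- NA_real_
    for (cc in num_cols) {
      s <- summarize_field_stats(block[[cc]])
      avg[[cc]] <- s$average
      sdv[[cc]] <- s$std_dev
    }
    rows[[length(rows) + 1L]] <- rbind(block, avg, sdv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gradient_table", "data.frame"))
}
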