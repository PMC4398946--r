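#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti that honour the pipeline's mm voxel sizes.
#' 4D data round-trips bit-identically (double precision on disk).
#'
#' @param series a [volume_series()] (or a 3D array for single maps).
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume_series()] (or 3D array when the file is 3D).
#' @export
write_volume <- function(series, path) {
  if (inherits(series, "volume_series")) {
    img <- RNifti::asNifti(structure(series$data,
                                     pixdim = c(series$voxel_mm, series$TR_s)),
                           datatype = "double")
  } else {
    img <- RNifti::asNifti(series, datatype = "double")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param path file path.
#' @param TA_s acquisition time to attach (not stored in NIfTI-1).
#' @export
read_volume <- function(path, TA_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  if (length(d) == 3L) return(array(as.vector(img), dim = d))
  TR <- if (length(pd) >= 4) pd[4] else 1
  volume_series(array(as.vector(img), dim = d), voxel_mm = pd[1:3],
                TR_s = TR, TA_s = if (is.null(TA_s)) TR else TA_s)
}

## ---- GIFTI (surface geometry, labels, functional values) ----------------
## Minimal ASCII-encoded GIFTI: enough to round-trip this package's meshes
## and per-vertex maps, readable by standard neuroimaging tools.

gifti_data_array <- function(doc, intent, datatype, data, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
                            Intent = intent, DataType = datatype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = as.character(length(dims)),
                            Encoding = "ASCII", Endian = "LittleEndian")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  fmt <- if (datatype == "NIFTI_TYPE_FLOAT64") "%.17g" else "%d"
  rows <- apply(matrix(data, nrow = dims[1], byrow = FALSE), 1,
                function(r) paste(sprintf(fmt, r), collapse = " "))
  xml2::xml_add_child(da, "Data", paste(rows, collapse = "\n"))
  da
}

gifti_metadata <- function(node, md) {
  m <- xml2::xml_add_child(node, "MetaData", .where = 0)
  for (nm in names(md)) {
    e <- xml2::xml_add_child(m, "MD")
    xml2::xml_add_child(e, "Name", nm)
    xml2::xml_add_child(e, "Value", as.character(md[[nm]]))
  }
}

#' Write a cortical mesh as a GIFTI surface file
#'
#' Stores the vertex coordinates (mm) and triangle indices as ASCII-encoded
#' GIFTI data arrays, with the hemisphere, anatomical axes and grid
#' geometry in the file metadata so [read_mesh()] restores the full object.
#'
#' @param mesh a `cortical_mesh`.
#' @param path output path (`.surf.gii` by convention).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_metadata(doc, list(
    hemisphere = mesh$hemisphere,
    anterior_axis = paste(sprintf("%.17g", mesh$axes$anterior), collapse = ","),
    lateral_axis = paste(sprintf("%.17g", mesh$axes$lateral), collapse = ","),
    grid_dim = paste(mesh$grid$dim, collapse = ","),
    grid_voxel_mm = paste(sprintf("%.17g", mesh$grid$voxel_mm), collapse = ","),
    grid_origin_mm = paste(sprintf("%.17g", mesh$grid$origin_mm), collapse = ","),
    spacing_mm = sprintf("%.17g", mesh$spacing_mm %||% 0),
    extent_mm = paste(sprintf("%.17g", mesh$extent_mm %||% c(0, 0)), collapse = ",")))
  gifti_data_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64",
                   mesh$vertices, dim(mesh$vertices))
  gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   mesh$triangles - 1L, dim(mesh$triangles))
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_num_csv <- function(x) as.numeric(strsplit(x, ",")[[1]])

gifti_read_array <- function(da) {
  dims <- as.integer(c(xml2::xml_attr(da, "Dim0"), xml2::xml_attr(da, "Dim1")))
  dims <- dims[!is.na(dims)]
  txt <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
  vals <- scan(text = txt, quiet = TRUE)
  if (length(dims) == 2L) {
    matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  } else vals
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  md_nodes <- xml2::xml_find_all(doc, "./MetaData/MD")
  md <- stats::setNames(
    lapply(md_nodes, function(n) xml2::xml_text(xml2::xml_find_first(n, "./Value"))),
    vapply(md_nodes, function(n) xml2::xml_text(xml2::xml_find_first(n, "./Name")), ""))
  das <- xml2::xml_find_all(doc, "./DataArray")
  intents <- vapply(das, function(d) xml2::xml_attr(d, "Intent"), "")
  verts_raw <- gifti_read_array(das[[which(intents == "NIFTI_INTENT_POINTSET")]])
  tris_raw <- gifti_read_array(das[[which(intents == "NIFTI_INTENT_TRIANGLE")]])
  vertices <- matrix(as.numeric(verts_raw), nrow = nrow(verts_raw))
  triangles <- matrix(as.integer(tris_raw), nrow = nrow(tris_raw)) + 1L
  structure(
    list(vertices = vertices, triangles = triangles,
         hemisphere = md$hemisphere,
         axes = list(anterior = parse_num_csv(md$anterior_axis),
                     lateral = parse_num_csv(md$lateral_axis)),
         grid = list(dim = as.integer(parse_num_csv(md$grid_dim)),
                     voxel_mm = parse_num_csv(md$grid_voxel_mm),
                     origin_mm = parse_num_csv(md$grid_origin_mm)),
         spacing_mm = as.numeric(md$spacing_mm),
         extent_mm = parse_num_csv(md$extent_mm)),
    class = "cortical_mesh")
}

#' Write per-vertex values or labels as GIFTI functional/label files
#'
#' @param values numeric (functional) or integer (label) per-vertex vector.
#' @param path output path (`.func.gii` / `.label.gii` by convention).
#' @param label_names optional names for integer labels, written as a
#'   GIFTI LabelTable.
#' @return `path`, invisibly.
#' @export
write_vertex_values <- function(values, path, label_names = NULL) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  if (!is.null(label_names)) {
    lt <- xml2::xml_add_child(doc, "LabelTable")
    for (i in seq_along(label_names)) {
      lab <- xml2::xml_add_child(lt, "Label", Key = as.character(i - 1L))
      xml2::xml_set_text(lab, label_names[i])
    }
    vals <- as.integer(values)
    vals[is.na(vals)] <- -1L
    gifti_data_array(doc, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                     vals, length(vals))
  } else {
    vals <- as.numeric(values)
    vals[is.na(vals)] <- NaN
    gifti_data_array(doc, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT64",
                     vals, length(vals))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_vertex_values
#' @export
read_vertex_values <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, "./DataArray")
  vals <- gifti_read_array(da)
  if (xml2::xml_attr(da, "Intent") == "NIFTI_INTENT_LABEL") {
    vals <- as.integer(vals)
    vals[vals < 0] <- NA_integer_
    lt <- xml2::xml_find_all(doc, "./LabelTable/Label")
    attr(vals, "labels") <- vapply(lt, xml2::xml_text, "")
  } else {
    vals[is.nan(vals)] <- NA_real_
  }
  vals
}

## ---- tables ---------------------------------------------------------------

#' Format p-values the way the summary tables print them
#'
#' Values below 1e-16 are reported as `"<1E-16"`; other values in
#' scientific notation. `parse_p` inverts the formatting, treating
#' `"<1E-16"` as an interval-censored value (returned as the bound, with a
#' `censored` attribute).
#'
#' @param p numeric p-values.
#' @return `format_p`: character; `parse_p`: numeric with attribute
#'   `censored` (logical).
#' @export
format_p <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < 1e-16, "<1E-16",
                       toupper(sprintf("%.2E", p))))
  out
}

#' @rdname format_p
#' @param x character p-value cells.
#' @export
parse_p <- function(x) {
  censored <- !is.na(x) & grepl("^<", x)
  val <- suppressWarnings(as.numeric(sub("^<", "", x)))
  structure(val, censored = censored)
}

#' Write / read the gradient summary table as TSV
#'
#' Degrees are printed with one decimal, R-squared with two, p-values in
#' the censored `"<1E-16"` convention. `read_gradient_table` parses the
#' file back; p columns come back as character cells so a write-read-write
#' round trip is byte-identical.
#'
#' @param table a `gradient_table` from [field_gradient_table()].
#' @param path output TSV path.
#' @return `path` / the parsed data frame.
#' @export
write_gradient_table <- function(table, path) {
  out <- as.data.frame(table)
  fmt <- function(x, f) ifelse(is.na(x), NA_character_, sprintf(f, x))
  for (cc in c("alpha_deg", "freq_dir_deg", "rate_dir_deg"))
    out[[cc]] <- fmt(as.numeric(out[[cc]]), "%.1f")
  for (cc in c("freq_r2", "rate_r2"))
    out[[cc]] <- fmt(as.numeric(out[[cc]]), "%.2f")
  for (cc in c("freq_p", "rate_p"))
    if (is.numeric(out[[cc]])) out[[cc]] <- format_p(out[[cc]])
  out$n_vertices <- fmt(as.numeric(out$n_vertices), "%.1f")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_gradient_table
#' @export
read_gradient_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "")
  for (cc in c("alpha_deg", "freq_dir_deg", "freq_r2", "rate_dir_deg",
               "rate_r2", "n_vertices"))
    df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Published per-hemisphere gradient directions for the core fields
#'
#' Reference table of gradient directions, fit statistics and relative
#' angles reported for fields A1, R and CL in both hemispheres of three
#' macaques (M1-M3), as printed in the study this pipeline models. Used by
#' the aggregation checks and the worked examples; the Average / Std-dev
#' rows are *not* included -- they are recomputed.
#'
#' @return Data frame with columns `animal`, `hemisphere`, `field`,
#'   `alpha_deg`, `freq_dir_deg`, `freq_r2`, `freq_p`, `rate_dir_deg`,
#'   `rate_r2`, `rate_p`, `n_vertices`.
#' @export
published_gradient_table <- function() {
  path <- system.file("extdata", "macaque_core_gradients.tsv",
                      package = "audtopo", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "")
  for (cc in c("alpha_deg", "freq_dir_deg", "freq_r2", "rate_dir_deg",
               "rate_r2", "n_vertices"))
    df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Write / read a plain TSV table
#'
#' @param table data frame.
#' @param path TSV path.
#' @return `path` / the data frame.
#' @export
write_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE)
}
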