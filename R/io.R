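#' Read and write surface meshes (GIFTI or plain text)
#'
#' Two dialects are supported. GIFTI surface files (`.surf.gii`) follow the
#' standard XML format with `NIFTI_INTENT_POINTSET` and
#' `NIFTI_INTENT_TRIANGLE` data arrays (ASCII, Base64Binary and
#' GZipBase64Binary encodings are read; ASCII is written). The plain-text
#' dialect is:
#'
#' ```
#' # optional comment lines
#' <n_vertices> <n_faces>
#' x y z            (n_vertices lines)
#' i j k            (n_faces lines, 0-based vertex indices)
#' ```
#'
#' File dialects store 0-based indices; the R objects are 1-based.
#'
#' @param path file path.
#' @param format `"gifti"`, `"plaintext"`, or `NULL` to infer from the
#'   extension (`.gii` means GIFTI).
#' @return `read_surface` returns a [surface_mesh()]; `write_surface` returns
#'   `path` invisibly.
#' @export
read_surface <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "gifti") {
    da <- read_gifti_arrays(path)
    pts <- da$arrays[[which(da$intents == "NIFTI_INTENT_POINTSET")[1]]]
    tri <- da$arrays[[which(da$intents == "NIFTI_INTENT_TRIANGLE")[1]]]
    if (is.null(pts) || is.null(tri)) {
      stop("GIFTI surface must contain POINTSET and TRIANGLE arrays: ", path)
    }
    return(surface_mesh(pts, tri + 1L))
  }
  lines <- read_data_lines(path)
  hdr <- scan(text = lines[1], quiet = TRUE)
  if (length(hdr) != 2L || any(hdr < 1)) {
    stop("malformed surface header (expected 'n_vertices n_faces'): ", path)
  }
  nv <- as.integer(hdr[1]); nf <- as.integer(hdr[2])
  if (length(lines) < 1L + nv + nf) {
    stop("surface file truncated: expected ", nv + nf, " data lines in ", path)
  }
  vmat <- parse_numeric_block(lines[2:(1 + nv)], 3L, path, "vertex")
  fmat <- parse_numeric_block(lines[(2 + nv):(1 + nv + nf)], 3L, path, "face")
  surface_mesh(vmat, fmat + 1L)
}

#' @rdname read_surface
#' @param mesh a [surface_mesh()].
#' @export
write_surface <- function(mesh, path, format = NULL) {
  stopifnot_mesh(mesh)
  format <- infer_format(path, format)
  if (format == "gifti") {
    write_gifti(path, list(
      list(intent = "NIFTI_INTENT_POINTSET", type = "NIFTI_TYPE_FLOAT32",
           data = mesh$vertices),
      list(intent = "NIFTI_INTENT_TRIANGLE", type = "NIFTI_TYPE_INT32",
           data = mesh$faces - 1L)
    ))
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gyralpeaks surface v1; face indices are 0-based", con)
  writeLines(paste(n_vertices(mesh), nrow(mesh$faces)), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(apply(mesh$faces - 1L, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read and write per-vertex metrics and label maps
#'
#' Plain-text metrics are one value per line (`NaN` or `NA` marks a missing
#' vertex); plain-text label maps are one non-negative integer per line, with
#' an optional embedded table of region names in header comments of the form
#' `#label <key> <name>`. GIFTI `.shape.gii`/`.func.gii` metric and
#' `.label.gii` label files are also supported.
#'
#' @param path file path.
#' @param mesh optional [surface_mesh()]; when supplied, the map length is
#'   checked against the mesh.
#' @param name metric tag passed to [scalar_map()].
#' @param format `"gifti"`, `"plaintext"`, or `NULL` to infer from extension.
#' @return [scalar_map()] or [label_map()]; writers return `path` invisibly.
#' @export
read_metric <- function(path, mesh = NULL, name = "other", format = NULL) {
  format <- infer_format(path, format)
  if (format == "gifti") {
    da <- read_gifti_arrays(path)
    vals <- as.numeric(da$arrays[[1]])
  } else {
    lines <- read_data_lines(path)
    vals <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(vals) & !(toupper(lines) %in% c("NAN", "NA")))
    if (length(bad) > 0L) {
      stop("unparseable metric value at data line ", bad[1], " of ", path)
    }
  }
  vals[is.nan(vals)] <- NA_real_
  out <- scalar_map(vals, name = name)
  if (!is.null(mesh)) check_aligned(out, mesh, path)
  out
}

#' @rdname read_metric
#' @param map a [scalar_map()] or [label_map()].
#' @export
write_metric <- function(map, path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "gifti") {
    write_gifti(path, list(list(intent = "NIFTI_INTENT_NONE",
                                type = "NIFTI_TYPE_FLOAT32",
                                data = matrix(map_values(map), ncol = 1))))
    return(invisible(path))
  }
  vals <- map_values(map)
  vals_chr <- ifelse(is.na(vals), "NaN",
                     format(vals, digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(c("# gyralpeaks metric v1; one value per vertex", vals_chr), path)
  invisible(path)
}

#' @rdname read_metric
#' @export
read_labels <- function(path, mesh = NULL, format = NULL) {
  format <- infer_format(path, format)
  if (format == "gifti") {
    da <- read_gifti_arrays(path)
    labs <- as.integer(da$arrays[[1]])
    out <- label_map(labs, table = da$label_table,
                     atlas_name = sub("\\.label\\.gii$|\\.gii$", "", basename(path)))
  } else {
    raw <- readLines(path, warn = FALSE)
    tab_lines <- grep("^#label ", raw, value = TRUE)
    table <- NULL
    if (length(tab_lines) > 0L) {
      parts <- strsplit(sub("^#label ", "", tab_lines), " ")
      table <- setNames(vapply(parts, function(p) paste(p[-1], collapse = " "), ""),
                        vapply(parts, `[`, "", 1))
    }
    lines <- strip_comments(raw)
    labs <- suppressWarnings(as.integer(lines))
    if (any(is.na(labs))) {
      stop("unparseable label at data line ", which(is.na(labs))[1], " of ", path)
    }
    out <- label_map(labs, table = table,
                     atlas_name = sub("\\.[^.]*$", "", basename(path)))
  }
  if (!is.null(mesh)) check_aligned(out, mesh, path)
  out
}

#' @rdname read_metric
#' @export
write_labels <- function(map, path, format = NULL) {
  format <- infer_format(path, format)
  table <- attr(map, "table")
  if (format == "gifti") {
    write_gifti(path, list(list(intent = "NIFTI_INTENT_LABEL",
                                type = "NIFTI_TYPE_INT32",
                                data = matrix(as.integer(map), ncol = 1))),
                label_table = table)
    return(invisible(path))
  }
  hdr <- c("# gyralpeaks labels v1; one integer per vertex; 0 = unassigned",
           paste("#label", names(table), unname(table)))
  writeLines(c(hdr, as.character(as.integer(map))), path)
  invisible(path)
}

#' Read and write vertex correspondence maps
#'
#' Two-column text: `source_vertex target_vertex`, 0-based, one line per
#' source vertex (every source vertex must be mapped).
#'
#' @param path file path.
#' @param n_source,n_target vertex counts of the two templates, used for
#'   validation when supplied.
#' @return `read_correspondence` returns an integer vector `mapping` (1-based,
#'   `mapping[v]` = target vertex of source vertex v) with attributes
#'   `source_species`/`target_species`.
#' @export
read_correspondence <- function(path, n_source = NULL, n_target = NULL) {
  lines <- read_data_lines(path)
  m <- parse_numeric_block(lines, 2L, path, "correspondence")
  src <- m[, 1] + 1L
  tgt <- m[, 2] + 1L
  n_src <- if (is.null(n_source)) max(src) else n_source
  if (!setequal(src, seq_len(n_src))) {
    stop("correspondence map must cover every source vertex exactly once: ", path)
  }
  mapping <- integer(n_src)
  mapping[src] <- tgt
  correspondence_map(mapping, n_target = n_target)
}

#' @rdname read_correspondence
#' @param mapping integer vector as returned by [correspondence_map()].
#' @export
write_correspondence <- function(mapping, path) {
  writeLines(c("# gyralpeaks correspondence v1; columns: source target (0-based)",
               paste(seq_along(mapping) - 1L, as.integer(mapping) - 1L)), path)
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("gifti", "plaintext")))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "plaintext"
}

strip_comments <- function(lines) {
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  strip_comments(readLines(path, warn = FALSE))
}

parse_numeric_block <- function(lines, ncol, path, what) {
  vals <- suppressWarnings(scan(text = lines, quiet = TRUE))
  if (anyNA(vals) || length(vals) != ncol * length(lines)) {
    stop("malformed ", what, " block in ", path)
  }
  matrix(vals, ncol = ncol, byrow = TRUE)
}

# --- minimal GIFTI XML support -------------------------------------------

gifti_r_type <- function(type) {
  switch(type,
         NIFTI_TYPE_FLOAT32 = ,
         NIFTI_TYPE_FLOAT64 = "double",
         NIFTI_TYPE_INT32 = ,
         NIFTI_TYPE_UINT8 = "integer",
         stop("unsupported GIFTI data type: ", type))
}

gifti_type_size <- function(type) {
  switch(type, NIFTI_TYPE_FLOAT32 = 4L, NIFTI_TYPE_FLOAT64 = 8L,
         NIFTI_TYPE_INT32 = 4L, NIFTI_TYPE_UINT8 = 1L)
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(das) == 0L) stop("no DataArray elements in GIFTI file: ", path)
  arrays <- list()
  intents <- character(length(das))
  for (ii in seq_along(das)) {
    da <- das[[ii]]
    at <- function(nm) xml2::xml_attr(da, nm)
    intents[ii] <- at("Intent")
    type <- at("DataType")
    enc <- at("Encoding")
    dim0 <- as.integer(at("Dim0"))
    dim1 <- if (!is.na(at("Dim1"))) as.integer(at("Dim1")) else 1L
    order <- at("ArrayIndexingOrder")
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    vals <- switch(
      enc,
      ASCII = scan(text = txt, quiet = TRUE),
      Base64Binary = decode_gifti_binary(txt, type, gzipped = FALSE),
      GZipBase64Binary = decode_gifti_binary(txt, type, gzipped = TRUE),
      stop("unsupported GIFTI encoding '", enc, "' in ", path)
    )
    if (length(vals) != dim0 * dim1) {
      stop("GIFTI DataArray ", ii, " has ", length(vals), " values, expected ",
           dim0 * dim1, " in ", path)
    }
    m <- if (identical(order, "ColumnMajorOrder")) {
      matrix(vals, nrow = dim0, ncol = dim1)
    } else {
      matrix(vals, nrow = dim0, ncol = dim1, byrow = TRUE)
    }
    if (gifti_r_type(type) == "integer") storage.mode(m) <- "integer"
    arrays[[ii]] <- m
  }
  lab_nodes <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  label_table <- NULL
  if (length(lab_nodes) > 0L) {
    keys <- xml2::xml_attr(lab_nodes, "Key")
    label_table <- setNames(xml2::xml_text(lab_nodes), keys)
    label_table <- label_table[keys != "0"]
  }
  list(arrays = arrays, intents = intents, label_table = label_table)
}

decode_gifti_binary <- function(txt, type, gzipped) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
  if (gzipped) raw <- memDecompress(raw, type = "gzip")
  n <- length(raw) %/% gifti_type_size(type)
  what <- gifti_r_type(type)
  readBin(raw, what = what, n = n, size = gifti_type_size(type),
          endian = "little")
}

write_gifti <- function(path, arrays, label_table = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">',
                     length(arrays)))
  if (!is.null(label_table)) {
    lines <- c(lines, "<LabelTable>",
               sprintf('<Label Key="%s">%s</Label>', names(label_table),
                       esc(unname(label_table))), "</LabelTable>")
  }
  for (a in arrays) {
    m <- a$data
    txt <- paste(apply(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                       1, paste, collapse = " "), collapse = "\n")
    lines <- c(lines, sprintf(
      paste0('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder=',
             '"RowMajorOrder" Dimensionality="%d" Dim0="%d" Dim1="%d" ',
             'Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ',
             'ExternalFileOffset="">'),
      a$intent, a$type, 2L, nrow(m), ncol(m)),
      "<Data>", txt, "</Data>", "</DataArray>")
  }
  lines <- c(lines, "</GIFTI>")
  writeLines(lines, path)
  invisible(path)
}
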