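#' Per-vertex scalar map
#'
#' A per-vertex real-valued metric aligned to a surface mesh (sulc, curvature,
#' thickness, myelin, local area, peak counts, ...). Missing values are `NA`;
#' all non-missing values must be finite.
#'
#' @param values numeric vector, one value per vertex.
#' @param name metric tag: one of `"sulc"`, `"curv"`, `"thickness"`,
#'   `"myelin"`, `"area"`, `"count"`, `"smoothed_count"`, `"other"`.
#' @param n_subjects for count maps, the number of subjects accumulated.
#' @return numeric vector of class `scalar_map` with attributes `name` and
#'   (optionally) `n_subjects`.
#' @export
scalar_map <- function(values, name = "other", n_subjects = NULL) {
  name <- match.arg(name, c("sulc", "curv", "thickness", "myelin", "area",
                            "count", "smoothed_count", "other"))
  values <- as.numeric(values)
  if (any(!is.finite(values) & !is.na(values))) {
    stop("non-missing scalar map values must be finite")
  }
  attr(values, "name") <- name
  if (!is.null(n_subjects)) {
    if (n_subjects < 1L) stop("`n_subjects` must be positive")
    attr(values, "n_subjects") <- as.integer(n_subjects)
  }
  class(values) <- c("scalar_map", "numeric")
  values
}

#' @export
print.scalar_map <- function(x, ...) {
  cat("scalar_map <", attr(x, "name"), ">: ", length(x), " vertices, ",
      sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

# strip class/attrs for arithmetic
map_values <- function(x) {
  y <- unclass(x)
  attributes(y) <- NULL
  y
}

check_aligned <- function(map, mesh, what = "map") {
  if (length(map) != n_vertices(mesh)) {
    stop(what, " has length ", length(map), " but mesh has ",
         n_vertices(mesh), " vertices")
  }
  invisible(map)
}

#' Per-vertex integer label map (atlas parcellation)
#'
#' Labels are non-negative integers aligned to a mesh; 0 means unassigned.
#' Every nonzero label in use must appear in `table`.
#'
#' @param labels integer vector of per-vertex labels (0 = unassigned).
#' @param table named character vector or `NULL`: `table[["<label>"]]` is the
#'   region name. If `NULL`, names `"region_<label>"` are generated.
#' @param atlas_name text tag for the atlas.
#' @return integer vector of class `label_map` with attributes `table` and
#'   `atlas_name`.
#' @export
label_map <- function(labels, table = NULL, atlas_name = "atlas") {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("labels must be non-negative integers")
  }
  used <- sort(unique(labels[labels > 0L]))
  if (is.null(table)) {
    table <- setNames(paste0("region_", used), as.character(used))
  }
  missing_lab <- setdiff(as.character(used), names(table))
  if (length(missing_lab) > 0L) {
    stop("labels missing from table: ", paste(missing_lab, collapse = ", "))
  }
  structure(labels, table = table, atlas_name = atlas_name,
            class = c("label_map", "integer"))
}

#' @export
print.label_map <- function(x, ...) {
  cat("label_map <", attr(x, "atlas_name"), ">: ", length(x), " vertices, ",
      length(unique(x[x > 0L])), " regions in use\n", sep = "")
  invisible(x)
}
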