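#' Triangle surface mesh
#'
#' Constructs and validates a triangle mesh, the substrate on which gyral
#' peaks are defined. Vertices are 3-D coordinates in millimetres; faces are
#' triples of vertex indices. Indices are 1-based in R; all file dialects
#' written and read by this package store 0-based indices (see
#' [read_surface()]).
#'
#' Validation enforces: every face index in range, no degenerate face
#' (repeated vertex), every edge shared by at most two faces, and every
#' vertex used by at least one face.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, and an internal cache environment.
#' @examples
#' tet <- surface_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
#' )
#' n_vertices(tet)
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    bad <- which(faces < 1L | faces > n, arr.ind = TRUE)[1, 1]
    stop("face ", bad, " refers to a vertex index outside [1, ", n, "]")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3])) {
    stop("degenerate face with a repeated vertex")
  }
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(ekey) > 2L)) stop("an edge belongs to more than two faces")
  if (length(setdiff(seq_len(n), unique(as.vector(faces)))) > 0L) {
    stop("vertex with no incident face: ",
         setdiff(seq_len(n), unique(as.vector(faces)))[1])
  }
  structure(
    list(vertices = vertices, faces = faces, cache = new.env(parent = emptyenv())),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' @rdname surface_mesh
#' @param mesh a `surface_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "surface_mesh")) stop("expected a `surface_mesh`")
  invisible(mesh)
}

#' Unique undirected edges of a mesh with Euclidean lengths
#'
#' @param mesh a `surface_mesh`.
#' @return tibble with columns `i`, `j` (1-based, i < j) and `length` (mm).
#' @export
mesh_edges <- function(mesh) {
  stopifnot_mesh(mesh)
  if (!is.null(mesh$cache$edges)) return(mesh$cache$edges)
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  i <- pmin(e[, 1], e[, 2])
  j <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(cbind(i, j))
  i <- i[keep]; j <- j[keep]
  d <- sqrt(rowSums((mesh$vertices[i, , drop = FALSE] -
                       mesh$vertices[j, , drop = FALSE])^2))
  out <- tibble::tibble(i = i, j = j, length = d)
  mesh$cache$edges <- out
  out
}

# sparse symmetric 0/1 adjacency (no diagonal)
mesh_adjacency <- function(mesh) {
  if (!is.null(mesh$cache$adjacency)) return(mesh$cache$adjacency)
  ed <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  a <- Matrix::sparseMatrix(i = c(ed$i, ed$j), j = c(ed$j, ed$i), x = 1,
                            dims = c(n, n))
  mesh$cache$adjacency <- a
  a
}

# weighted igraph over mesh edges, edge weight = Euclidean length
mesh_graph <- function(mesh) {
  if (!is.null(mesh$cache$graph)) return(mesh$cache$graph)
  ed <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(cbind(ed$i, ed$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_vertices(mesh) - igraph::vcount(g)))
  igraph::E(g)$weight <- ed$length
  mesh$cache$graph <- g
  g
}

#' k-ring neighborhood of a vertex
#'
#' All vertices reachable from `v` by at most `k` mesh edges, excluding `v`
#' itself.
#'
#' @param mesh a `surface_mesh`.
#' @param v vertex index (1-based).
#' @param k positive integer ring size.
#' @return sorted integer vector of vertex indices.
#' @export
k_ring <- function(mesh, v, k) {
  stopifnot_mesh(mesh)
  n <- n_vertices(mesh)
  if (length(v) != 1L || is.na(v) || v < 1L || v > n) {
    stop("invalid vertex index: ", v)
  }
  if (k < 1L) stop("`k` must be >= 1")
  rings <- k_ring_matrix(mesh, k)
  sort(rings@i[(rings@p[v] + 1L):rings@p[v + 1L]] + 1L)
}

# sparse pattern matrix of the k-ring: entry (u, v) present iff u is within
# k edges of v, u != v. Column v holds the ring of v. Cached per (mesh, k).
k_ring_matrix <- function(mesh, k) {
  key <- paste0("rings_", k)
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  a <- mesh_adjacency(mesh)
  n <- nrow(a)
  step <- a + Matrix::Diagonal(n)
  acc <- step
  kk <- k
  # repeated squaring on the boolean pattern
  pow <- step
  acc <- if (kk %% 2L == 1L) pow else Matrix::Diagonal(n)
  kk <- kk %/% 2L
  while (kk > 0L) {
    pow <- pow %*% pow
    pow@x[] <- 1
    if (kk %% 2L == 1L) {
      acc <- acc %*% pow
      acc@x[] <- 1
    }
    kk <- kk %/% 2L
  }
  acc <- methods::as(acc, "CsparseMatrix")
  diag(acc) <- 0
  acc <- Matrix::drop0(acc)
  mesh$cache[[key]] <- acc
  acc
}

#' Geodesic distance between mesh vertices
#'
#' Shortest path along mesh edges, with edge weight equal to Euclidean edge
#' length (Dijkstra on the edge graph). This is the standard surface-tooling
#' approximation, not an exact polyhedral geodesic.
#'
#' @param mesh a `surface_mesh`.
#' @param a,b vertex indices (1-based); `geodesic_distance` takes scalars,
#'   `geodesic_distances` takes vectors and returns a matrix.
#' @return distance in mm. Errors if the two vertices are in different
#'   connected components.
#' @export
geodesic_distance <- function(mesh, a, b) {
  d <- geodesic_distances(mesh, a, b)[1, 1]
  if (!is.finite(d)) stop("vertices ", a, " and ", b, " are unreachable from each other")
  d
}

#' @rdname geodesic_distance
#' @param from,to vectors of vertex indices.
#' @export
geodesic_distances <- function(mesh, from, to = seq_len(n_vertices(mesh))) {
  stopifnot_mesh(mesh)
  n <- n_vertices(mesh)
  if (any(from < 1L | from > n) || any(to < 1L | to > n)) {
    stop("invalid vertex index")
  }
  g <- mesh_graph(mesh)
  uf <- unique(from)
  ut <- unique(to)
  d <- igraph::distances(g, v = uf, to = ut, algorithm = "dijkstra")
  d[match(from, uf), match(to, ut), drop = FALSE]
}

#' Local surface area map
#'
#' For each vertex i, the mean area S_i of its incident triangles, divided by
#' the whole-mesh mean of S_i, giving a unitless per-vertex expansion ratio
#' whose global mean is 1.
#'
#' @param mesh a `surface_mesh`.
#' @return a [scalar_map()] named `"area"`.
#' @export
local_surface_area <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  v <- mesh$vertices
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  farea <- 0.5 * sqrt(rowSums(cr^2))
  idx <- as.vector(f)
  s_sum <- rowsum(rep(farea, 3L), idx, reorder = TRUE)
  s_cnt <- rowsum(rep(1, 3L * nrow(f)), idx, reorder = TRUE)
  si <- numeric(n_vertices(mesh))
  si[as.integer(rownames(s_sum))] <- s_sum / s_cnt
  scalar_map(si / mean(si), name = "area")
}
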