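#' Anisotropic (similarity-weighted) smoothing of a count map
#'
#' Perona-Malik-style neighborhood averaging: at each iteration every vertex
#' value is replaced by a weighted mean over its ring neighborhood plus
#' itself, with weights `w(u, v) = exp(-(value(u) - value(v))^2 / (2 beta^2))`.
#' Similar values average together while sharp steps are preserved, so the
#' extrema that the watershed needs survive smoothing. The operator is a
#' convex combination: it never produces negative values from a non-negative
#' input and never raises the global maximum.
#'
#' @param mesh a [surface_mesh()].
#' @param count a [scalar_map()] aligned to `mesh` (typically the peak count
#'   map).
#' @param iterations non-negative number of smoothing passes (0 = identity).
#' @param ring neighborhood ring size used for the averaging (default 1).
#' @param beta positive similarity bandwidth, in count units. Default 2:
#'   count steps much larger than ~2 subjects are treated as edges and
#'   preserved.
#' @return a [scalar_map()] named `"smoothed_count"`.
#' @export
anisotropic_smooth <- function(mesh, count, iterations = 3, ring = 1,
                               beta = 2) {
  stopifnot_mesh(mesh)
  check_aligned(count, mesh, "count")
  if (iterations < 0) stop("`iterations` must be >= 0")
  if (beta <= 0) stop("`beta` must be positive")
  x <- map_values(count)
  if (iterations == 0) {
    return(scalar_map(x, name = "smoothed_count",
                      n_subjects = attr(count, "n_subjects")))
  }
  rings <- k_ring_matrix(mesh, ring)
  # triplets (u in ring of v) plus the self pair (v, v)
  v_idx <- c(rep.int(seq_len(ncol(rings)), diff(rings@p)),
             seq_len(ncol(rings)))
  u_idx <- c(rings@i + 1L, seq_len(ncol(rings)))
  inv2b2 <- 1 / (2 * beta^2)
  for (it in seq_len(iterations)) {
    w <- exp(-(x[u_idx] - x[v_idx])^2 * inv2b2)
    num <- rowsum(w * x[u_idx], v_idx, reorder = TRUE)
    den <- rowsum(w, v_idx, reorder = TRUE)
    x <- as.numeric(num / den)
  }
  scalar_map(x, name = "smoothed_count", n_subjects = attr(count, "n_subjects"))
}

#' Group-wise peak clusters by watershed flooding
#'
#' Descending-value flooding of the smoothed count map. Vertices with
#' smoothed value > `flood_floor` are visited in strictly decreasing value
#' order (ties broken by ascending vertex index). A vertex with no labeled
#' 1-ring neighbor founds a new basin; a vertex with labeled neighbors joins
#' the basin of its highest-valued labeled neighbor. When a vertex touches
#' two (or more) basins it is a saddle: for each pair, the basin with the
#' smaller peak height merges into the other if
#' `peak(smaller) - saddle_height < saddle_ratio * peak(smaller)`, otherwise
#' the boundary stands and the vertex joins the higher-peak side. Basins
#' whose raw-count mass is below `min_mass` are discarded. The cluster center
#' is the basin's argmax of smoothed value (ties to the lowest index).
#'
#' @param mesh a [surface_mesh()].
#' @param smoothed smoothed count map ([scalar_map()]).
#' @param raw_count raw count map; cluster mass is summed from it.
#' @param flood_floor only vertices with smoothed value strictly above this
#'   are flooded (default 0).
#' @param min_mass minimum raw-count mass for a basin to survive (default 2,
#'   i.e. supported by at least two subject peaks).
#' @param saddle_ratio relative-prominence merge threshold in (0, 1)
#'   (default 0.15).
#' @param species,hemisphere metadata stored on the result.
#' @return a `peak_clusters` tibble with one row per cluster: `cluster_id`,
#'   `center` (vertex), `mass`, `n_vertices`, `vertices` (list-column of
#'   vertex index vectors); attributes `species`, `hemisphere`, `n_subjects`.
#' @export
watershed_clusters <- function(mesh, smoothed, raw_count,
                               flood_floor = 0, min_mass = 2,
                               saddle_ratio = 0.15,
                               species = "synthetic", hemisphere = "L") {
  stopifnot_mesh(mesh)
  check_aligned(smoothed, mesh, "smoothed")
  check_aligned(raw_count, mesh, "raw_count")
  x <- map_values(smoothed)
  raw <- map_values(raw_count)
  active <- which(!is.na(x) & x > flood_floor)
  lab <- integer(length(x))                 # 0 = unlabeled
  if (length(active) > 0L) {
    ord <- active[order(-x[active], active)]
    adj <- mesh_adjacency(mesh)
    parent <- integer(0)                    # union-find over basin ids
    peak_h <- numeric(0)
    uf_find <- function(b) {
      while (parent[b] != b) {
        parent[b] <<- parent[parent[b]]
        b <- parent[b]
      }
      b
    }
    nbr_of <- function(v) adj@i[(adj@p[v] + 1L):adj@p[v + 1L]] + 1L
    for (v in ord) {
      nb <- nbr_of(v)
      nl <- lab[nb]
      labeled <- nb[nl > 0L]
      if (length(labeled) == 0L) {
        b <- length(parent) + 1L
        parent[b] <- b
        peak_h[b] <- x[v]
        lab[v] <- b
        next
      }
      roots <- unique(vapply(lab[labeled], uf_find, 0L))
      # basin of the highest-valued labeled neighbor (ties: lowest index)
      best_nb <- labeled[order(-x[labeled], labeled)][1]
      target <- uf_find(lab[best_nb])
      if (length(roots) > 1L) {
        saddle <- x[v]
        for (b in setdiff(roots, target)) {
          lo <- if (peak_h[b] <= peak_h[target]) b else target
          if (peak_h[lo] - saddle < saddle_ratio * peak_h[lo]) {
            hi <- if (lo == b) target else b
            parent[lo] <- hi
            peak_h[hi] <- max(peak_h[hi], peak_h[lo])
            target <- uf_find(target)
          }
        }
      }
      lab[v] <- target
    }
    lab[lab > 0L] <- vapply(lab[lab > 0L], uf_find, 0L)
  }
  basins <- sort(unique(lab[lab > 0L]))
  rows <- lapply(basins, function(b) {
    verts <- which(lab == b)
    mass <- sum(raw[verts])
    if (mass < min_mass) return(NULL)
    center <- verts[order(-x[verts], verts)][1]
    tibble::tibble(center = center, mass = mass,
                   n_vertices = length(verts), vertices = list(verts))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows) == 0L) {
    tibble::tibble(cluster_id = integer(), center = integer(),
                   mass = numeric(), n_vertices = integer(),
                   vertices = list())
  } else {
    dplyr::bind_rows(rows) |>
      dplyr::mutate(cluster_id = dplyr::row_number(), .before = 1)
  }
  peak_clusters(out, species = species, hemisphere = hemisphere,
                n_subjects = attr(raw_count, "n_subjects"))
}

#' Peak cluster set constructor
#'
#' @param clusters tibble with columns `cluster_id`, `center`, `mass`,
#'   `n_vertices`, `vertices` (list of integer vectors).
#' @param species,hemisphere,n_subjects metadata.
#' @return tibble of class `peak_clusters`. Vertex sets must be pairwise
#'   disjoint and each center must belong to its vertex set.
#' @export
peak_clusters <- function(clusters, species = "synthetic", hemisphere = "L",
                          n_subjects = NULL) {
  clusters <- tibble::as_tibble(clusters)
  need <- c("cluster_id", "center", "mass", "n_vertices", "vertices")
  if (!all(need %in% names(clusters))) {
    stop("`clusters` must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(clusters$cluster_id)) stop("cluster_ids must be unique")
  allv <- unlist(clusters$vertices)
  if (anyDuplicated(allv)) stop("cluster vertex sets must be pairwise disjoint")
  if (nrow(clusters) > 0L &&
        !all(mapply(function(c, v) c %in% v, clusters$center,
                    clusters$vertices))) {
    stop("every cluster center must lie in its own vertex set")
  }
  structure(clusters, species = species, hemisphere = hemisphere,
            n_subjects = n_subjects,
            class = c("peak_clusters", class(tibble::tibble())))
}
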