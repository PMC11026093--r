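#' Patch parcellation of a surface
#'
#' Contiguous, approximately equal-size patches by farthest-point seeding on
#' the mesh geodesic graph followed by nearest-seed assignment (ties go to
#' the earlier seed). Deterministic given `seed`.
#'
#' @param mesh a [surface_mesh()].
#' @param n_patches number of patches (<= number of vertices).
#' @param seed integer RNG seed (selects the first farthest-point seed).
#' @param fixed_seeds optional vertex indices forced to be the first patch
#'   seeds (used by the synthetic atlas generator to pin region layouts to
#'   planted loci); the remaining seeds are placed by farthest-point
#'   sampling.
#' @return integer vector of class `parcellation`: `patch_of[v]` in
#'   `1..n_patches`, with attributes `n_patches` and `seeds`.
#' @export
patch_parcellate <- function(mesh, n_patches, seed = 1L, fixed_seeds = NULL) {
  stopifnot_mesh(mesh)
  n <- n_vertices(mesh)
  if (n_patches > n) stop("`n_patches` cannot exceed the vertex count")
  if (n_patches < 1L) stop("`n_patches` must be >= 1")
  fixed_seeds <- unique(as.integer(fixed_seeds))
  if (length(fixed_seeds) > n_patches) {
    stop("more fixed seeds than patches")
  }
  g <- mesh_graph(mesh)
  seeds <- integer(n_patches)
  n_fixed <- length(fixed_seeds)
  if (n_fixed > 0L) {
    seeds[seq_len(n_fixed)] <- fixed_seeds
  } else {
    set.seed(seed)
    seeds[1] <- sample.int(n, 1L)
    n_fixed <- 1L
  }
  best_d <- as.numeric(igraph::distances(g, v = seeds[1]))
  assign <- rep(1L, n)
  for (s in seq_len(n_patches)[-1]) {
    if (s > n_fixed) seeds[s] <- which.max(best_d)  # ties -> lowest index
    d <- as.numeric(igraph::distances(g, v = seeds[s]))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    assign[upd] <- s
  }
  structure(assign, n_patches = as.integer(n_patches), seeds = seeds,
            class = c("parcellation", "integer"))
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", attr(x, "n_patches"), "patches over", length(x),
      "vertices\n")
  invisible(x)
}

#' Connectivity graph constructor
#'
#' @param weights symmetric non-negative matrix with zero diagonal.
#' @param kind `"functional"` or `"structural"`.
#' @param thresholded has top-fraction thresholding been applied?
#' @param fraction the retained fraction if thresholded.
#' @return matrix of class `connectivity_graph`.
#' @export
connectivity_graph <- function(weights, kind = c("functional", "structural"),
                               thresholded = FALSE, fraction = NULL) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  finite <- weights[is.finite(weights)]
  if (max(abs(weights - t(weights)), na.rm = TRUE) > 1e-12) {
    stop("weights must be symmetric")
  }
  if (any(diag(weights) != 0, na.rm = TRUE)) stop("diagonal must be zero")
  structure(weights, kind = kind, thresholded = thresholded,
            fraction = fraction,
            class = c("connectivity_graph", "matrix", "array"))
}

graph_weights <- function(g) {
  w <- unclass(g)
  attr(w, "kind") <- NULL; attr(w, "thresholded") <- NULL
  attr(w, "fraction") <- NULL
  w
}

#' Functional connectivity matrix from time series
#'
#' Per-patch mean time series, pairwise Pearson correlation, and Fisher
#' z-transformation (`atanh`), with correlations clipped to
#' `±(1 - 1e-7)` before the transform. Negative z values are kept at this
#' stage. Patches with a constant series get missing rows/columns (flagged
#' with a warning).
#'
#' @param timeseries numeric matrix, rows = patches (when `parc` is `NULL`)
#'   or vertices (when `parc` is given), columns = timepoints (>= 3).
#' @param parc optional [patch_parcellate()] result mapping rows to patches.
#' @return a [connectivity_graph()] (functional, unthresholded); entries are
#'   Fisher z values, diagonal 0, `NA` rows for constant patches.
#' @export
fc_matrix <- function(timeseries, parc = NULL) {
  ts <- as.matrix(timeseries)
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  if (!is.null(parc)) {
    if (nrow(ts) != length(parc)) {
      stop("time-series rows must match the parcellation length")
    }
    ts <- rowsum(ts, group = as.integer(parc), reorder = TRUE)
    ts <- ts / as.vector(table(as.integer(parc)))
  }
  const <- apply(ts, 1, function(r) sd(r) == 0)
  if (any(const)) {
    warning(sum(const), " constant patch series; their connectivity is missing")
    ts[const, ] <- NA_real_
  }
  r <- suppressWarnings(cor(t(ts)))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  connectivity_graph(z, kind = "functional", thresholded = FALSE)
}

#' Structural connectivity matrix from streamline endpoints
#'
#' Entry (i, j) counts the endpoint pairs with one vertex in patch i and the
#' other in patch j (i != j); same-patch pairs land on the (zero) diagonal
#' and are dropped.
#'
#' @param endpoint_pairs two-column matrix or data frame of vertex indices
#'   (1-based), one streamline per row.
#' @param parc a [patch_parcellate()] result.
#' @return a [connectivity_graph()] (structural, unthresholded).
#' @export
sc_matrix <- function(endpoint_pairs, parc) {
  ep <- as.matrix(endpoint_pairs)
  np <- attr(parc, "n_patches")
  w <- matrix(0, np, np)
  if (nrow(ep) > 0L) {
    if (any(ep < 1L | ep > length(parc))) stop("endpoint vertex out of range")
    pi_ <- as.integer(parc)[ep[, 1]]
    pj <- as.integer(parc)[ep[, 2]]
    keep <- pi_ != pj
    tab <- table(factor(pmin(pi_, pj)[keep], levels = seq_len(np)),
                 factor(pmax(pi_, pj)[keep], levels = seq_len(np)))
    w <- matrix(as.numeric(tab), np, np)
    w <- w + t(w)
  }
  connectivity_graph(w, kind = "structural", thresholded = FALSE)
}

#' Element-wise group average of connectivity graphs
#'
#' @param graphs list of [connectivity_graph()] objects of the same kind and
#'   shape.
#' @return a [connectivity_graph()] with the element-wise mean weights.
#' @export
group_average <- function(graphs) {
  if (length(graphs) == 0L) stop("no graphs to average")
  kind <- attr(graphs[[1]], "kind")
  dims <- dim(graphs[[1]])
  for (g in graphs) {
    if (!identical(dim(g), dims) || !identical(attr(g, "kind"), kind)) {
      stop("graphs must share shape and kind")
    }
  }
  m <- Reduce(`+`, lapply(graphs, graph_weights)) / length(graphs)
  connectivity_graph(m, kind = kind, thresholded = FALSE)
}

#' Retain the top fraction of each row's connections
#'
#' Per row, the `ceiling(fraction * (n - 1))` largest off-diagonal entries
#' are kept (ties broken by ascending column index) and the rest zeroed; the
#' result is then symmetrized by the element-wise maximum, i.e. the union of
#' row-wise survivors. Because the LARGEST values are kept, strongly negative
#' Fisher-z edges are zeroed by construction.
#'
#' @param graph an unthresholded [connectivity_graph()].
#' @param fraction fraction of connections to retain per row, in (0, 1\];
#'   default 0.10.
#' @return a thresholded, symmetric [connectivity_graph()].
#' @export
threshold_top <- function(graph, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  w <- graph_weights(graph)
  n <- nrow(w)
  keep_k <- ceiling(fraction * (n - 1))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- w[i, ]
    row[i] <- -Inf
    ord <- order(-row, seq_len(n))
    keep <- ord[seq_len(keep_k)]
    keep <- keep[is.finite(row[keep]) & !is.na(row[keep])]
    out[i, keep] <- row[keep]
  }
  out <- pmax(out, t(out))
  connectivity_graph(out, kind = attr(graph, "kind"), thresholded = TRUE,
                     fraction = fraction)
}

#' Nodal graph metrics
#'
#' The five nodal metrics of weighted brain-network analysis, computed with
#' the conventions of the standard connectome toolkits:
#' * `degree`: number of nonzero neighbors (binarized);
#' * `strength`: sum of edge weights;
#' * `clustering_coef`: Onnela weighted clustering coefficient with weights
#'   rescaled by the maximum weight;
#' * `betweenness`: unnormalized shortest-path betweenness over unordered
#'   pairs, endpoints excluded, on edge lengths `1/weight`;
#' * `efficiency`: nodal efficiency `mean_j 1/d(i, j)` on lengths
#'   `1/weight`; unreachable nodes contribute 0.
#'
#' @param graph a thresholded, symmetric, non-negative
#'   [connectivity_graph()].
#' @return tibble with columns `node`, `degree`, `strength`,
#'   `clustering_coef`, `betweenness`, `efficiency`.
#' @export
node_metrics <- function(graph) {
  w <- graph_weights(graph)
  if (any(w < 0, na.rm = TRUE)) stop("metrics need non-negative weights")
  w[is.na(w)] <- 0
  n <- nrow(w)
  degree <- rowSums(w > 0)
  strength <- rowSums(w)
  wmax <- max(w)
  cc <- numeric(n)
  if (wmax > 0) {
    wh <- (w / wmax)^(1 / 3)
    num <- diag(wh %*% wh %*% wh)
    denom <- degree * (degree - 1)
    cc <- ifelse(denom > 0, num / denom, 0)
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  btw <- if (igraph::ecount(g) > 0) {
    igraph::betweenness(g, weights = len, normalized = FALSE)
  } else {
    numeric(n)
  }
  d <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = len)
  } else {
    matrix(Inf, n, n)
  }
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  efficiency <- rowSums(inv) / max(1, n - 1)
  tibble::tibble(node = seq_len(n), degree = degree, strength = strength,
                 clustering_coef = cc, betweenness = as.numeric(btw),
                 efficiency = efficiency)
}

#' Compare nodal metrics of shared vs unique peaks
#'
#' Each classed subject peak inherits the nodal metrics of the patch that
#' contains it; metrics are then averaged per subject per class and compared
#' with the pooled two-sample t-test, FDR-corrected across metrics. Peaks in
#' patches without metrics (dropped patches) are excluded with a warning.
#'
#' @param classed_peaks list (one element per subject) of tibbles as returned
#'   by [individual_class_peaks()].
#' @param parc a [patch_parcellate()] result on the same template.
#' @param metrics table from [node_metrics()].
#' @return `feature_comparison` tibble, one row per metric, with `p_fdr`.
#' @export
peak_node_props <- function(classed_peaks, parc, metrics) {
  metric_names <- setdiff(names(metrics), "node")
  patch_of <- as.integer(parc)
  valid <- metrics$node
  n_dropped <- 0L
  per_subject <- purrr::map(classed_peaks, function(cp) {
    cp <- cp[cp$class %in% c("shared", "unique"), , drop = FALSE]
    cp$patch <- patch_of[cp$vertex]
    drop <- !(cp$patch %in% valid)
    n_dropped <<- n_dropped + sum(drop)
    cp[!drop, , drop = FALSE]
  })
  if (n_dropped > 0L) {
    warning(n_dropped, " peaks in dropped patches excluded")
  }
  rows <- purrr::map(metric_names, function(mn) {
    vals <- setNames(metrics[[mn]], metrics$node)
    ms <- vapply(per_subject, function(cp) {
      x <- vals[as.character(cp$patch[cp$class == "shared"])]
      if (length(x) == 0L) NA_real_ else mean(x)
    }, 0)
    mu <- vapply(per_subject, function(cp) {
      x <- vals[as.character(cp$patch[cp$class == "unique"])]
      if (length(x) == 0L) NA_real_ else mean(x)
    }, 0)
    compare_classes(ms, mu, feature_name = mn)
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_bh(out$p_value)
  class(out) <- c("feature_comparison", class(tibble::tibble()))
  out
}
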