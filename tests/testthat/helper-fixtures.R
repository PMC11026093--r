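# Shared fixtures and independent oracles, built in code at test time.

tetrahedron <- function() {
  surface_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  )
}

# memoised icospheres (meshes carry their own neighborhood caches)
.fixture_env <- new.env()
fixture_icosphere <- function(subdivisions, radius = 1) {
  key <- paste0("ico_", subdivisions, "_", radius)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- icosphere(subdivisions, radius)
  }
  .fixture_env[[key]]
}

# valid "random" mesh: icosphere with seeded radial + tangential jitter
random_mesh <- function(subdivisions = 3, radius = 10, seed = 1,
                        jitter = 0.05) {
  base <- icosphere(subdivisions, radius)
  set.seed(seed)
  v <- base$vertices * (1 + runif(nrow(base$vertices), -jitter, jitter))
  v <- v + matrix(rnorm(length(v), sd = jitter * radius / 4), ncol = 3)
  surface_mesh(v, base$faces)
}

# strip of triangles: n_edges + 1 rungs, unit spacing; vertices 2k-1 / 2k
# form rung k, so vertex 1 -> vertex (2*n_edges+1) is n_edges edges along
# the bottom row with unit edge length
strip_mesh <- function(n_edges = 5) {
  k <- n_edges + 1
  v <- rbind(cbind(seq_len(k) - 1, 0, 0), cbind(seq_len(k) - 1, 1, 0))
  f <- do.call(rbind, lapply(seq_len(n_edges), function(i) {
    rbind(c(i, i + 1, k + i), c(i + 1, k + i + 1, k + i))
  }))
  surface_mesh(v, f)
}

# boolean adjacency-matrix-power BFS oracle for k_ring
k_ring_oracle <- function(mesh, v, k) {
  ed <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  A <- matrix(FALSE, n, n)
  A[cbind(ed$i, ed$j)] <- TRUE
  A[cbind(ed$j, ed$i)] <- TRUE
  reach <- logical(n)
  reach[v] <- TRUE
  for (step in seq_len(k)) {
    reach <- reach | (colSums(A[reach, , drop = FALSE]) > 0)
  }
  sort(setdiff(which(reach), v))
}

# Floyd-Warshall all-pairs shortest paths on the edge-weighted mesh graph
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- w
  for (kk in seq_len(n)) {
    d <- pmin(d, outer(d[, kk], d[kk, ], `+`))
  }
  d
}

mesh_weight_matrix <- function(mesh) {
  ed <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  w <- matrix(Inf, n, n)
  diag(w) <- 0
  w[cbind(ed$i, ed$j)] <- ed$length
  w[cbind(ed$j, ed$i)] <- ed$length
  w
}

# direct per-face accumulation oracle for local surface area
local_area_oracle <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  tri_area <- function(a, b, c) {
    ab <- b - a; ac <- c - a
    0.5 * sqrt(sum(crossprod_vec(ab, ac)^2))
  }
  crossprod_vec <- function(x, y) {
    c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
      x[1] * y[2] - x[2] * y[1])
  }
  areas <- apply(f, 1, function(fr) tri_area(v[fr[1], ], v[fr[2], ], v[fr[3], ]))
  si <- vapply(seq_len(nrow(v)), function(i) {
    mean(areas[apply(f == i, 1, any)])
  }, 0)
  si / mean(si)
}

# exhaustive k-ring scan oracle for peak detection
detect_peaks_oracle <- function(mesh, sulc, k, gyral_quantile = 0.5) {
  s <- as.numeric(sulc)
  thr <- quantile(s, gyral_quantile, na.rm = TRUE, names = FALSE)
  which(vapply(seq_len(n_vertices(mesh)), function(v) {
    if (is.na(s[v]) || s[v] > thr) return(FALSE)
    nb <- k_ring(mesh, v, k)
    if (anyNA(s[nb])) return(FALSE)
    all(s[v] < s[nb])
  }, TRUE))
}

# slow, scan-based re-implementation of the watershed flooding rules
watershed_oracle <- function(mesh, smoothed, raw, flood_floor = 0,
                             min_mass = 0, saddle_ratio = 0.15) {
  x <- as.numeric(smoothed)
  raw <- as.numeric(raw)
  n <- n_vertices(mesh)
  nbrs <- lapply(seq_len(n), function(v) k_ring(mesh, v, 1))
  active <- which(!is.na(x) & x > flood_floor)
  ord <- active[order(-x[active], active)]
  lab <- integer(n)
  peak_of <- numeric(0)
  next_id <- 0L
  relabel <- function(from, to) lab[lab == from] <<- to
  for (v in ord) {
    labeled <- nbrs[[v]][lab[nbrs[[v]]] > 0L]
    if (length(labeled) == 0L) {
      next_id <- next_id + 1L
      peak_of[next_id] <- x[v]
      lab[v] <- next_id
      next
    }
    best_nb <- labeled[order(-x[labeled], labeled)][1]
    target <- lab[best_nb]
    basins <- unique(lab[labeled])
    for (b in setdiff(basins, target)) {
      lo <- if (peak_of[b] <= peak_of[target]) b else target
      hi <- if (lo == b) target else b
      if (peak_of[lo] - x[v] < saddle_ratio * peak_of[lo]) {
        relabel(lo, hi)
        peak_of[hi] <- max(peak_of[hi], peak_of[lo])
        target <- if (target == lo) hi else target
      }
    }
    lab[v] <- target
  }
  keep <- Filter(function(b) sum(raw[lab == b]) >= min_mass,
                 sort(unique(lab[lab > 0L])))
  lapply(keep, function(b) {
    verts <- which(lab == b)
    list(vertices = verts, center = verts[order(-x[verts], verts)][1],
         mass = sum(raw[verts]))
  })
}

# exhaustive one-to-one matching maximizing (count, sum of dice), over all
# assignments of candidate pairs; feasible for <= 6x6 candidate sets
exhaustive_match_oracle <- function(cand, na, nb) {
  best <- list(count = -1, dice = -Inf)
  recurse <- function(i, used_a, used_b, count, dsum) {
    if (i > nrow(cand)) {
      if (count > best$count ||
            (count == best$count && dsum > best$dice + 1e-12)) {
        best <<- list(count = count, dice = dsum)
      }
      return(invisible())
    }
    # skip pair i
    recurse(i + 1, used_a, used_b, count, dsum)
    a <- cand$ai[i]; b <- cand$bi[i]
    if (!used_a[a] && !used_b[b]) {
      used_a[a] <- TRUE; used_b[b] <- TRUE
      recurse(i + 1, used_a, used_b, count + 1, dsum + cand$dice[i])
    }
    invisible()
  }
  recurse(1, logical(na), logical(nb), 0, 0)
  best
}

# textbook formula oracles for the statistical kernels ---------------------

pooled_t_oracle <- function(xs, ys) {
  nx <- length(xs); ny <- length(ys)
  sp2 <- ((nx - 1) * var(xs) + (ny - 1) * var(ys)) / (nx + ny - 2)
  t <- (mean(xs) - mean(ys)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

welch_t_oracle <- function(xs, ys) {
  nx <- length(xs); ny <- length(ys)
  vx <- var(xs) / nx; vy <- var(ys) / ny
  t <- (mean(xs) - mean(ys)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tt <- slope / se
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2,
       p_slope = 2 * pt(-abs(tt), n - 2))
}

# brute-force nodal graph metric oracle for small weighted graphs:
# Floyd-Warshall distances plus exhaustive simple-path enumeration for
# shortest-path counts (betweenness), independent of igraph
node_metrics_oracle <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  d <- floyd_warshall(len)
  degree <- rowSums(w > 0)
  strength <- rowSums(w)
  wh <- (w / max(w))^(1 / 3)
  cc <- vapply(seq_len(n), function(i) {
    k <- degree[i]
    if (k < 2) return(0)
    tot <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) tot <- tot + wh[i, j] * wh[i, h] * wh[j, h]
    }
    tot / (k * (k - 1))
  }, 0)
  # enumerate all simple paths s -> t with length pruning by FW distances
  count_paths <- function(s, t) {
    n_sp <- 0
    through <- numeric(n)
    walk <- function(v, visited, length_so_far, interior) {
      if (length_so_far + d[v, t] > d[s, t] + 1e-9) return(invisible())
      if (v == t) {
        n_sp <<- n_sp + 1
        through[interior] <<- through[interior] + 1
        return(invisible())
      }
      for (u in which(len[v, ] < Inf)) {
        if (u != v && !visited[u]) {
          vis2 <- visited; vis2[u] <- TRUE
          walk(u, vis2, length_so_far + len[v, u],
               if (u == t) interior else c(interior, u))
        }
      }
      invisible()
    }
    vis <- logical(n); vis[s] <- TRUE
    walk(s, vis, 0, integer(0))
    list(sigma = n_sp, through = through)
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    cp <- count_paths(s, t)
    if (cp$sigma > 0) btw <- btw + cp$through / cp$sigma
  }
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  list(degree = degree, strength = strength, clustering_coef = cc,
       betweenness = btw, efficiency = rowSums(inv) / (n - 1))
}

random_connectivity_graph <- function(n, seed, density = 0.5) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- ifelse(runif(sum(up)) < density, runif(sum(up), 0.1, 1), 0)
  w[up] <- vals
  w <- w + t(w)
  connectivity_graph(w, kind = "functional", thresholded = TRUE,
                     fraction = density)
}

# small helper: quick synthetic design for pipeline mechanics tests;
# overrides in ... replace the reduced defaults
small_design <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    n_subjects = 14L,
    mesh_human = list(subdivisions = 4L, radius = 80),
    mesh_macaque = list(subdivisions = 4L, radius = 35),
    bump_sigma = c(human = 9, macaque = 4),
    n_patches = c(human = 60L, macaque = 60L),
    timeseries = list(n_timepoints = 300L, n_communities = 10L, rho = 0.7),
    atlas_resolutions = c(24L, 48L),
    genes = list(n_shared = 30L, n_unique = 34L, n_other = 10L,
                 n_genes = 80L, n_informative = 4L, effect_d = 2)
  )
  do.call(synthetic_design, utils::modifyList(args, list(...)))
}
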