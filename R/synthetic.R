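#' Icosphere template mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere. Used as the
#' synthetic stand-in for a hemisphere template: gyral peaks are defined on
#' the sulc FIELD, so the carrier geometry can stay simple while the scalar
#' maps carry the structure.
#'
#' @param subdivisions number of 4-to-1 face subdivisions (0 = icosahedron).
#'   Subdivision 4 has 2562 vertices, 5 has 10242.
#' @param radius sphere radius in mm.
#' @return a [surface_mesh()].
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ukey <- unique(ekey)
    eu <- do.call(rbind, strsplit(ukey, " "))
    storage.mode(eu) <- "integer"
    mid <- v[eu[, 1], , drop = FALSE] + v[eu[, 2], , drop = FALSE]
    mid <- mid / sqrt(rowSums(mid^2))
    mid_id <- nrow(v) + match(ekey, ukey)
    v <- rbind(v, mid)
    m12 <- mid_id[seq_len(nrow(f))]
    m23 <- mid_id[nrow(f) + seq_len(nrow(f))]
    m13 <- mid_id[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(m12, f[, 2], m23),
               cbind(m13, m23, f[, 3]),
               cbind(m12, m23, m13))
  }
  surface_mesh(v * radius, f)
}

#' Synthetic study design
#'
#' Declares every parameter of the synthetic two-species data set: mesh
#' templates, planted gyral loci (paired shared loci plus per-species unique
#' loci on well-separated directions), per-subject jitter and noise, the
#' patch time-series model, atlas resolutions, and the planted gene table.
#' All generators are pure functions of the design (which carries the seed).
#'
#' Planted loci sit on distinct dodecahedron-vertex directions, which are
#' pairwise >= 41.8 degrees apart, so unique loci of one species lie far
#' (>= 3 x 7 mm) from every opposite-species locus image under the generated
#' correspondence, while shared loci are paired across species by direction.
#'
#' @param seed master RNG seed; all generators derive from it.
#' @param n_subjects subjects per species.
#' @param n_shared,n_unique planted shared / per-species-unique locus counts
#'   (n_shared + 2 * n_unique <= 20).
#' @param shared_amplitude,unique_amplitude sulc bump depths (shared deeper,
#'   planting the larger peak-height magnitude of shared peaks).
#' @param bump_sigma named Gaussian bump widths in mm per species.
#' @param presence named per-class probabilities that a locus is expressed in
#'   a given subject (defaults shared = 0.95, unique = 0.80): folding
#'   landmarks are not present in every individual, and species-shared ones
#'   are the more consistent class, planting the higher inter-subject
#'   consistency of shared clusters.
#' @param jitter_rings per-subject locus jitter in mesh edges (default 1).
#' @param noise_sd sd of the spatially smoothed per-subject noise field
#'   (default 0.1 = 10% of the unique bump amplitude).
#' @param rotation_deg rigid rotation (about z) between the two templates,
#'   undone by the generated correspondence map.
#' @param mesh_human,mesh_macaque lists with `subdivisions` and `radius` (mm).
#' @param n_patches named per-species patch counts for the connectome stage.
#' @param timeseries list: `n_timepoints`, `n_communities`, `rho`
#'   (within-community correlation).
#' @param atlas_resolutions region counts for the synthetic atlases.
#' @param genes list: `n_shared`, `n_unique`, `n_other` region counts,
#'   `n_genes`, `n_informative`, `effect_d` (standardized mean shift of
#'   informative genes between shared- and unique-labeled regions).
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(
    seed = 1L,
    n_subjects = 20L,
    n_shared = 6L,
    n_unique = 4L,
    shared_amplitude = 1.2,
    unique_amplitude = 1.0,
    presence = c(shared = 0.95, unique = 0.80),
    bump_sigma = c(human = 6, macaque = 4),
    jitter_rings = 1L,
    noise_sd = 0.1,
    rotation_deg = 8,
    mesh_human = list(subdivisions = 5L, radius = 80),
    mesh_macaque = list(subdivisions = 4L, radius = 35),
    n_patches = c(human = 150L, macaque = 100L),
    timeseries = list(n_timepoints = 600L, n_communities = 12L, rho = 0.7),
    atlas_resolutions = c(24L, 60L, 120L),
    genes = list(n_shared = 55L, n_unique = 65L, n_other = 30L,
                 n_genes = 200L, n_informative = 5L, effect_d = 2)) {
  if (n_shared + 2L * n_unique > 20L) {
    stop("at most 20 well-separated locus directions are available")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  design <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_shared = as.integer(n_shared),
                 n_unique = as.integer(n_unique),
                 shared_amplitude = shared_amplitude,
                 unique_amplitude = unique_amplitude,
                 presence = presence,
                 bump_sigma = bump_sigma, jitter_rings = as.integer(jitter_rings),
                 noise_sd = noise_sd, rotation_deg = rotation_deg,
                 mesh = list(human = mesh_human, macaque = mesh_macaque),
                 n_patches = n_patches, timeseries = timeseries,
                 atlas_resolutions = atlas_resolutions, genes = genes)
  class(design) <- "synthetic_design"
  design
}

# 20 unit directions (dodecahedron vertices), pairwise >= 41.8 degrees apart
dodecahedron_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  s <- c(-1, 1)
  cube <- as.matrix(expand.grid(x = s, y = s, z = s))
  d <- rbind(cube,
             cbind(0, rep(s, each = 2) / phi, rep(s, 2) * phi),
             cbind(rep(s, each = 2) / phi, rep(s, 2) * phi, 0),
             cbind(rep(s, each = 2) * phi, 0, rep(s, 2) / phi))
  d / sqrt(rowSums(d^2))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

# locus directions in the HUMAN frame; macaque loci use the back-rotated
# directions so that the correspondence (rotation + rescale) re-aligns them.
design_loci_directions <- function(design) {
  d <- dodecahedron_directions()
  ns <- design$n_shared; nu <- design$n_unique
  list(shared = d[seq_len(ns), , drop = FALSE],
       unique_human = d[ns + seq_len(nu), , drop = FALSE],
       unique_macaque = d[ns + nu + seq_len(nu), , drop = FALSE])
}

nearest_vertex_by_direction <- function(mesh, directions) {
  vdir <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  as.integer(apply(directions, 1, function(u) which.max(vdir %*% u)))
}

# great-circle distance (mm) from every mesh vertex to one vertex; the
# synthetic templates are (nearly) spheres, so this is the exact geodesic.
sphere_geodesic_to <- function(mesh, v, radius) {
  vdir <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  cosang <- pmin(pmax(vdir %*% vdir[v, ], -1), 1)
  radius * acos(as.numeric(cosang))
}

# iid Gaussian field smoothed by `passes` rounds of 1-ring averaging, then
# rescaled to sd `target_sd`; emulates the spatially smooth residual
# variation of registered surface maps.
smooth_noise_field <- function(mesh, target_sd, passes = 2L) {
  n <- n_vertices(mesh)
  x <- rnorm(n)
  if (target_sd == 0) return(numeric(n))
  a <- mesh_adjacency(mesh)
  deg <- Matrix::rowSums(a)
  for (i in seq_len(passes)) {
    x <- (x + as.numeric(a %*% x)) / (deg + 1)
  }
  x * (target_sd / sd(x))
}

#' Generate one synthetic species
#'
#' Builds the species template (an icosphere with small radial expansions at
#' shared loci and contractions at unique loci, which drive the local surface
#' area pattern), the planted locus table, and per-subject maps: sulc
#' (baseline wide depressions at the template loci, minus a narrow
#' per-subject bump at a jittered center per locus, plus smooth noise), and
#' the anatomical feature maps (curv, area; plus thickness and myelin for the
#' human-like species) with the planted shared-vs-unique contrasts.
#'
#' @param design a [synthetic_design()].
#' @param species `"human"` or `"macaque"`.
#' @return list with `mesh`, `loci` (tibble: `locus_id`, `class`, `vertex`,
#'   `amplitude`, `sigma`), and `subjects`: a list of per-subject lists of
#'   [scalar_map()]s (`sulc`, `curv`, `area`, and for human `thickness`,
#'   `myelin`).
#' @export
make_species <- function(design, species = c("human", "macaque")) {
  species <- match.arg(species)
  spec_mesh <- design$mesh[[species]]
  radius <- spec_mesh$radius
  sigma <- design$bump_sigma[[species]]
  if (3 * sigma > pi * radius) stop("locus radius exceeds the mesh extent")
  dirs <- design_loci_directions(design)
  ldir <- rbind(dirs$shared,
                if (species == "human") dirs$unique_human else dirs$unique_macaque)
  if (species == "macaque") {
    ldir <- ldir %*% rotation_z(design$rotation_deg)   # back-rotated frame
  }
  cls <- c(rep("shared", design$n_shared), rep("unique", design$n_unique))
  base_sphere <- icosphere(spec_mesh$subdivisions, radius)
  lv <- nearest_vertex_by_direction(base_sphere, ldir)
  # radial area perturbation: +10% radius at shared loci, -5% at unique
  gd0 <- vapply(lv, function(v) sphere_geodesic_to(base_sphere, v, radius),
                numeric(n_vertices(base_sphere)))
  area_eps <- ifelse(cls == "shared", 0.10, -0.05)
  bump_shape <- exp(-gd0^2 / (2 * (1.5 * sigma)^2))
  rfac <- 1 + as.numeric(bump_shape %*% area_eps)
  mesh <- surface_mesh(base_sphere$vertices * rfac, base_sphere$faces)
  amp <- ifelse(cls == "shared", design$shared_amplitude,
                design$unique_amplitude)
  loci <- tibble::tibble(locus_id = seq_along(lv), class = cls,
                         vertex = as.integer(lv), amplitude = amp,
                         sigma = sigma)
  # per-locus narrow and wide bump shapes at the template centers; a locus a
  # subject expresses contributes both (a wide gyral depression plus the
  # sharp crown), an absent locus contributes neither
  narrow0 <- exp(-gd0^2 / (2 * sigma^2))
  wide0 <- exp(-gd0^2 / (2 * (2 * sigma)^2))
  species_seed <- design$seed * 1000L + match(species, c("human", "macaque"))
  set.seed(species_seed)
  n <- n_vertices(mesh)
  subjects <- vector("list", design$n_subjects)
  jit_ring <- if (design$jitter_rings > 0L) {
    k_ring_matrix(mesh, design$jitter_rings)
  }
  for (s in seq_len(design$n_subjects)) {
    centers <- vapply(lv, function(v) {
      if (design$jitter_rings == 0L) return(v)
      cand <- c(v, jit_ring@i[(jit_ring@p[v] + 1L):jit_ring@p[v + 1L]] + 1L)
      cand[sample.int(length(cand), 1L)]
    }, 0L)
    present <- runif(length(lv)) < design$presence[cls]
    bumps <- vapply(seq_along(centers), function(i) {
      if (!present[i]) return(numeric(n))
      amp[i] * (exp(-sphere_geodesic_to(mesh, centers[i], radius)^2 /
                      (2 * sigma^2)) + 0.5 * wide0[, i])
    }, numeric(n))
    sulc <- -rowSums(bumps) + smooth_noise_field(mesh, design$noise_sd)
    curv_delta <- ifelse(cls == "shared", -0.10, 0.05)
    curv <- 0.5 + as.numeric(narrow0 %*% curv_delta) +
      smooth_noise_field(mesh, 0.02)
    area <- map_values(local_surface_area(mesh)) +
      smooth_noise_field(mesh, 0.01)
    maps <- list(
      sulc = scalar_map(sulc, name = "sulc"),
      curv = scalar_map(curv, name = "curv"),
      area = scalar_map(area, name = "area")
    )
    if (species == "human") {
      thick_delta <- ifelse(cls == "shared", -0.25, 0.10)
      myel_delta <- ifelse(cls == "shared", 0.30, -0.05)
      maps$thickness <- scalar_map(
        2.8 + as.numeric(narrow0 %*% thick_delta) +
          smooth_noise_field(mesh, 0.03), name = "thickness")
      maps$myelin <- scalar_map(
        1.5 + as.numeric(narrow0 %*% myel_delta) +
          smooth_noise_field(mesh, 0.03), name = "myelin")
    }
    subjects[[s]] <- maps
  }
  list(mesh = mesh, loci = loci, subjects = subjects, species = species)
}

#' Generate the cross-species vertex correspondence
#'
#' Nearest-vertex map between the two synthetic templates after undoing the
#' known rigid rotation and radial rescale that relate them: each source
#' direction is rotated into the target frame and mapped to the target vertex
#' with the largest direction cosine. Paired shared loci map within 7 mm by
#' construction.
#'
#' @param design a [synthetic_design()].
#' @param source,target the species meshes as returned by [make_species()]
#'   (only their meshes are used). Defaults regenerate them.
#' @param direction `"macaque_to_human"` (the study's projection direction)
#'   or `"human_to_macaque"`.
#' @return a [correspondence_map()].
#' @export
make_correspondence <- function(design,
                                direction = c("macaque_to_human",
                                              "human_to_macaque"),
                                source = NULL, target = NULL) {
  direction <- match.arg(direction)
  src_sp <- if (direction == "macaque_to_human") "macaque" else "human"
  tgt_sp <- setdiff(c("human", "macaque"), src_sp)
  src_mesh <- if (is.null(source)) {
    icosphere(design$mesh[[src_sp]]$subdivisions, design$mesh[[src_sp]]$radius)
  } else {
    source$mesh
  }
  tgt_mesh <- if (is.null(target)) {
    icosphere(design$mesh[[tgt_sp]]$subdivisions, design$mesh[[tgt_sp]]$radius)
  } else {
    target$mesh
  }
  rot <- rotation_z(design$rotation_deg)
  if (direction == "human_to_macaque") rot <- t(rot)
  sdir <- src_mesh$vertices / sqrt(rowSums(src_mesh$vertices^2))
  sdir <- sdir %*% t(rot)
  tdir <- tgt_mesh$vertices / sqrt(rowSums(tgt_mesh$vertices^2))
  mapping <- max.col(sdir %*% t(tdir), ties.method = "first")
  correspondence_map(mapping, source_species = src_sp,
                     target_species = tgt_sp,
                     n_target = n_vertices(tgt_mesh))
}

#' Generate patch community time series
#'
#' Community-structured signals: every patch carries a latent community
#' signal mixed with idiosyncratic noise (within-community correlation
#' `rho`); hub patches (those containing shared locus centers) instead carry
#' an equal mixture of all community signals, so after top-fraction
#' thresholding their degree and strength exceed the median. One matrix per
#' subject.
#'
#' @param design a [synthetic_design()].
#' @param parc a [patch_parcellate()] result on the species template.
#' @param hub_patches integer vector of hub patch indices (e.g. the patches
#'   containing shared locus centers).
#' @param n_subjects number of per-subject matrices (default from design).
#' @param seed_offset integer added to the design seed (lets the two species
#'   draw independent series).
#' @return list with `series` (list of patches x timepoints matrices),
#'   `community` (patch community assignment) and `hubs`.
#' @export
make_timeseries <- function(design, parc, hub_patches = integer(),
                            n_subjects = design$n_subjects,
                            seed_offset = 0L) {
  np <- attr(parc, "n_patches")
  ts_spec <- design$timeseries
  tt <- ts_spec$n_timepoints
  nc <- ts_spec$n_communities
  rho <- ts_spec$rho
  set.seed(design$seed * 1000L + 97L + seed_offset)
  community <- rep_len(seq_len(nc), np)[sample.int(np)]
  hubs <- sort(unique(as.integer(hub_patches)))
  series <- lapply(seq_len(n_subjects), function(s) {
    g <- matrix(rnorm(nc * tt), nc, tt)
    x <- matrix(rnorm(np * tt), np, tt) * sqrt(1 - rho)
    common <- sqrt(rho) * g[community, , drop = FALSE]
    x <- x + common
    if (length(hubs) > 0L) {
      hub_sig <- sqrt(rho) * (colSums(g) / sqrt(nc))
      x[hubs, ] <- matrix(rnorm(length(hubs) * tt), ncol = tt) *
        sqrt(1 - rho) + rep(hub_sig, each = length(hubs))
    }
    x
  })
  list(series = series, community = community, hubs = hubs)
}

#' Generate streamline endpoint pairs (structural connectivity)
#'
#' Endpoint pairs connect vertices of patch pairs: mostly within-community
#' pairs, with a boosted rate of connections involving hub patches, mirroring
#' the planted functional hub structure.
#'
#' @param design a [synthetic_design()].
#' @param parc a [patch_parcellate()] result.
#' @param community per-patch community assignment (from
#'   [make_timeseries()]).
#' @param hub_patches hub patch indices.
#' @param n_pairs number of streamlines (default 5000).
#' @param hub_fraction fraction of streamlines with at least one hub endpoint
#'   (default 0.3).
#' @param seed_offset added to the design seed.
#' @return two-column integer matrix of vertex indices.
#' @export
make_endpoints <- function(design, parc, community, hub_patches,
                           n_pairs = 5000L, hub_fraction = 0.3,
                           seed_offset = 0L) {
  set.seed(design$seed * 1000L + 131L + seed_offset)
  np <- attr(parc, "n_patches")
  verts_of <- split(seq_along(parc), as.integer(parc))
  pick_vertex <- function(p) {
    v <- verts_of[[as.character(p)]]
    v[sample.int(length(v), 1L)]
  }
  hubs <- as.integer(hub_patches)
  pairs <- matrix(0L, n_pairs, 2)
  for (i in seq_len(n_pairs)) {
    if (length(hubs) > 0L && runif(1) < hub_fraction) {
      p1 <- hubs[sample.int(length(hubs), 1L)]
      p2 <- sample.int(np, 1L)
    } else {
      p1 <- sample.int(np, 1L)
      same <- which(community == community[p1])
      p2 <- same[sample.int(length(same), 1L)]
    }
    pairs[i, ] <- c(pick_vertex(p1), pick_vertex(p2))
  }
  pairs
}

#' Generate synthetic atlases
#'
#' One [label_map()] per requested resolution, built by farthest-point patch
#' parcellation with a distinct seed per atlas, plus a named 12-network atlas
#' (`networks`) whose regions carry the standard lower/higher-order network
#' names for [network_tally()].
#'
#' When `loci` is supplied, the region layout is pinned to the planted
#' ground truth: each shared locus center gets two flanking parcellation
#' seeds (so a region boundary bisects it and its ring neighborhood spans
#' several regions), while each unique locus center is itself a seed (so it
#' sits in a region interior) — planting the higher region diversity of
#' shared peaks.
#'
#' @param design a [synthetic_design()].
#' @param mesh the species template mesh.
#' @param loci optional loci tibble from [make_species()].
#' @return named list of [label_map()] objects (`atlas_<n>` and `networks`).
#' @export
make_atlases <- function(design, mesh, loci = NULL) {
  res <- design$atlas_resolutions
  fixed <- if (!is.null(loci)) atlas_fixed_seeds(mesh, loci) else NULL
  atlases <- lapply(seq_along(res), function(i) {
    parc <- patch_parcellate(mesh, res[i], seed = design$seed * 100L + i,
                             fixed_seeds = fixed)
    label_map(as.integer(parc), atlas_name = paste0("atlas_", res[i]))
  })
  names(atlases) <- paste0("atlas_", res)
  net_names <- c("V1", "V2", "Aud", "SMN", "PMN", "VMN", "OAN",
                 "CON", "DAN", "Lan", "FPN", "DMN")
  parc12 <- patch_parcellate(mesh, 12L, seed = design$seed * 100L + 99L)
  atlases$networks <- label_map(
    as.integer(parc12),
    table = setNames(net_names, as.character(seq_len(12L))),
    atlas_name = "networks")
  atlases
}

# two near-antipodal ring-2 flankers per shared locus (boundary bisects the
# locus), the center itself per unique locus (region interior)
atlas_fixed_seeds <- function(mesh, loci) {
  seeds <- integer(0)
  for (i in seq_len(nrow(loci))) {
    c0 <- loci$vertex[i]
    if (loci$class[i] == "shared") {
      ring2 <- setdiff(k_ring(mesh, c0, 2L), k_ring(mesh, c0, 1L))
      a <- ring2[1]
      d <- sqrt(rowSums((mesh$vertices[ring2, , drop = FALSE] -
                           matrix(mesh$vertices[a, ], length(ring2), 3,
                                  byrow = TRUE))^2))
      b <- ring2[which.max(d)]
      seeds <- c(seeds, a, b)
    } else {
      seeds <- c(seeds, c0)
    }
  }
  unique(seeds)
}

#' Generate a region x gene expression table with planted class effects
#'
#' Background expression is N(0, 1); each informative gene is shifted by
#' +d/2 in shared-labeled regions and -d/2 in unique-labeled regions.
#'
#' @param design a [synthetic_design()] (its `genes` spec is used).
#' @param region_class optional tibble with columns `region` and `class`
#'   (e.g. from [label_regions()]); when `NULL`, region classes are
#'   synthesized from the design's region counts.
#' @param seed_offset added to the design seed.
#' @return list with `expression` (matrix, rownames = region ids, colnames =
#'   gene symbols), `region_class` (tibble), `informative_genes` (character).
#' @export
make_gene_table <- function(design, region_class = NULL, seed_offset = 0L) {
  gs <- design$genes
  set.seed(design$seed * 1000L + 211L + seed_offset)
  if (is.null(region_class)) {
    region_class <- tibble::tibble(
      region = seq_len(gs$n_shared + gs$n_unique + gs$n_other),
      class = c(rep("shared", gs$n_shared), rep("unique", gs$n_unique),
                rep("other", gs$n_other))
    )
  }
  nr <- nrow(region_class)
  genes <- sprintf("gene_%03d", seq_len(gs$n_genes))
  informative <- genes[seq_len(gs$n_informative)]
  X <- matrix(rnorm(nr * gs$n_genes), nr, gs$n_genes,
              dimnames = list(as.character(region_class$region), genes))
  shift <- ifelse(region_class$class == "shared", gs$effect_d / 2,
                  ifelse(region_class$class == "unique", -gs$effect_d / 2, 0))
  X[, informative] <- X[, informative] + shift
  list(expression = X, region_class = region_class,
       informative_genes = informative)
}

#' Ground-truth disc of a planted locus
#'
#' The vertex set a recovered cluster is scored against: all vertices within
#' `jitter_rings + 1` mesh edges of the template locus center — where subject
#' peaks can land (the per-subject jitter plus one ring of noise-induced
#' detection slack), hence where the locus' count mass accumulates.
#'
#' @param mesh the species template mesh.
#' @param center template locus center vertex.
#' @param jitter_rings the design's jitter (default 1).
#' @return sorted integer vertex set including the center.
#' @export
planted_disc <- function(mesh, center, jitter_rings = 1L) {
  sort(c(center, k_ring(mesh, center, jitter_rings + 1L)))
}
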