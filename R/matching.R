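#' Vertex correspondence map between two templates
#'
#' A total per-source-vertex map onto target-template vertices, standing in
#' for a cross-species surface registration (which is consumed, not computed,
#' by this package).
#'
#' @param mapping integer vector: `mapping[v]` is the target vertex (1-based)
#'   of source vertex v. Every source vertex must be mapped.
#' @param source_species,target_species text tags.
#' @param n_target target template vertex count, for validation.
#' @return integer vector of class `correspondence_map`.
#' @export
correspondence_map <- function(mapping, source_species = "macaque",
                               target_species = "human", n_target = NULL) {
  mapping <- as.integer(mapping)
  if (anyNA(mapping) || any(mapping < 1L)) {
    stop("correspondence mapping must be total with valid target indices")
  }
  if (!is.null(n_target) && any(mapping > n_target)) {
    stop("correspondence mapping exceeds target vertex count")
  }
  structure(mapping, source_species = source_species,
            target_species = target_species,
            class = c("correspondence_map", "integer"))
}

#' Map a cluster's vertex set through a correspondence map
#'
#' @param vertices integer vector of source-template vertex indices (a
#'   cluster's vertex set).
#' @param correspondence a [correspondence_map()].
#' @return sorted unique target vertex indices (duplicates collapse).
#' @export
map_cluster <- function(vertices, correspondence) {
  vertices <- as.integer(vertices)
  if (any(vertices < 1L | vertices > length(correspondence))) {
    stop("cluster vertex outside the correspondence map's source template")
  }
  sort(unique(as.integer(correspondence)[vertices]))
}

#' Map a whole cluster set onto the target template
#'
#' Vertex sets are mapped elementwise (duplicates collapse) and each center
#' maps to `correspondence[center]`.
#'
#' @param clusters a [peak_clusters()] tibble on the source template.
#' @param correspondence a [correspondence_map()].
#' @return a `peak_clusters` tibble on the target template; `n_vertices` is
#'   the mapped (collapsed) set size.
#' @export
map_cluster_set <- function(clusters, correspondence) {
  mapped <- dplyr::mutate(
    tibble::as_tibble(clusters),
    vertices = purrr::map(.data$vertices, map_cluster,
                          correspondence = correspondence),
    center = as.integer(correspondence)[.data$center],
    n_vertices = lengths(.data$vertices)
  )
  peak_clusters(mapped, species = attr(clusters, "species"),
                hemisphere = attr(clusters, "hemisphere"),
                n_subjects = attr(clusters, "n_subjects"))
}

#' Dice overlap of two vertex sets
#'
#' `2 |A intersect B| / (|A| + |B|)`. Undefined (an error) when both sets are
#' empty.
#'
#' @param a,b integer vectors of vertex indices.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (length(a) + length(b) == 0L) stop("Dice of two empty sets is undefined")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Split two cluster sets into species-shared and species-unique
#'
#' A candidate pair (a, b) qualifies iff their Dice overlap is > 0 OR the
#' geodesic distance between their centers on the target template is below
#' `d_max` (default 7 mm). Matching is one-to-one: candidate pairs are sorted
#' by descending Dice, ties by ascending center distance, then by ids, and
#' accepted greedily if neither cluster is already matched. Unmatched
#' clusters are each species' unique clusters.
#'
#' @param clusters_a cluster set of species A on the target template
#'   (typically the target species' own clusters).
#' @param clusters_b cluster set of species B already mapped onto the target
#'   template (see [map_cluster_set()]).
#' @param mesh_target the target template mesh (for center geodesics).
#' @param d_max center geodesic distance criterion in mm (default 7).
#' @return object of class `cluster_match`: a list with
#'   `matches` (tibble: `cluster_a_id`, `cluster_b_id`, `dice`,
#'   `center_distance`, `criterion_met`), `shared_a`, `unique_a`, `shared_b`,
#'   `unique_b` (peak_clusters tibbles).
#' @export
match_shared <- function(clusters_a, clusters_b, mesh_target, d_max = 7) {
  if (!identical(attr(clusters_a, "hemisphere"), attr(clusters_b, "hemisphere"))) {
    stop("cluster sets are from different hemispheres")
  }
  a <- tibble::as_tibble(clusters_a)
  b <- tibble::as_tibble(clusters_b)
  cand <- tidyr::expand_grid(ai = seq_len(nrow(a)), bi = seq_len(nrow(b)))
  if (nrow(cand) > 0L) {
    cd <- geodesic_distances(mesh_target, a$center, b$center)
    cand$dice <- purrr::map2_dbl(cand$ai, cand$bi, function(i, j) {
      dice(a$vertices[[i]], b$vertices[[j]])
    })
    cand$center_distance <- cd[cbind(cand$ai, cand$bi)]
    cand <- cand[cand$dice > 0 | cand$center_distance < d_max, , drop = FALSE]
  } else {
    cand$dice <- numeric(0)
    cand$center_distance <- numeric(0)
  }
  cand <- cand[order(-cand$dice, cand$center_distance,
                     a$cluster_id[cand$ai], b$cluster_id[cand$bi]), ,
               drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$ai[r]; j <- cand$bi[r]
    if (!used_a[i] && !used_b[j]) {
      keep[r] <- TRUE
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  acc <- cand[keep, , drop = FALSE]
  matches <- tibble::tibble(
    cluster_a_id = a$cluster_id[acc$ai],
    cluster_b_id = b$cluster_id[acc$bi],
    dice = acc$dice,
    center_distance = acc$center_distance,
    criterion_met = dplyr::case_when(
      acc$dice > 0 & acc$center_distance < d_max ~ "both",
      acc$dice > 0 ~ "dice",
      TRUE ~ "distance"
    )
  )
  subset_pc <- function(cl, ids, negate = FALSE) {
    sel <- if (negate) !(cl$cluster_id %in% ids) else cl$cluster_id %in% ids
    peak_clusters(tibble::as_tibble(cl)[sel, , drop = FALSE],
                  species = attr(cl, "species"),
                  hemisphere = attr(cl, "hemisphere"),
                  n_subjects = attr(cl, "n_subjects"))
  }
  structure(
    list(matches = matches,
         shared_a = subset_pc(clusters_a, matches$cluster_a_id),
         unique_a = subset_pc(clusters_a, matches$cluster_a_id, negate = TRUE),
         shared_b = subset_pc(clusters_b, matches$cluster_b_id),
         unique_b = subset_pc(clusters_b, matches$cluster_b_id, negate = TRUE),
         d_max = d_max),
    class = "cluster_match"
  )
}

#' @export
print.cluster_match <- function(x, ...) {
  cat("cluster_match:", nrow(x$matches), "shared pairs;",
      nrow(x$unique_a), "unique in A;", nrow(x$unique_b), "unique in B\n")
  invisible(x)
}

#' Inter-subject consistency of a cluster
#'
#' Summed raw peak count over the cluster's vertices divided by the number of
#' subjects: the mean number of peaks per subject captured by the cluster.
#'
#' @param vertices the cluster's vertex set.
#' @param raw_count raw count map with attribute `n_subjects` (or supply
#'   `n_subjects`).
#' @param n_subjects overrides the count map attribute if given.
#' @return non-negative real.
#' @export
consistency <- function(vertices, raw_count, n_subjects = NULL) {
  ns <- if (!is.null(n_subjects)) n_subjects else attr(raw_count, "n_subjects")
  if (is.null(ns) || ns == 0) stop("number of subjects must be positive")
  sum(map_values(raw_count)[as.integer(vertices)]) / ns
}

#' Cross-species regression of shared-cluster consistency
#'
#' Ordinary least squares of the target-species (e.g. human) consistency on
#' the source-species (e.g. macaque) consistency over matched shared pairs,
#' with the Pearson correlation, R-squared and the two-sided p-value for the
#' slope.
#'
#' @param consistency_b source-species consistency per shared pair (x).
#' @param consistency_a target-species consistency per shared pair (y).
#' @param hemisphere metadata tag.
#' @return one-row tibble of class `consistency_fit`: `hemisphere`, `n`,
#'   `pcc`, `slope`, `intercept`, `r_squared`, `p_value`, `degenerate`.
#' @export
consistency_regression <- function(consistency_b, consistency_a,
                                   hemisphere = "L") {
  x <- as.numeric(consistency_b)
  y <- as.numeric(consistency_a)
  if (length(x) != length(y)) stop("consistency vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 shared pairs for the regression")
  degenerate <- sd(y) == 0 || sd(x) == 0
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  co <- s$coefficients
  out <- tibble::tibble(
    hemisphere = hemisphere,
    n = length(x),
    pcc = if (degenerate) NA_real_ else cor(x, y),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (degenerate) NA_real_ else s$r.squared,
    p_value = if (degenerate || nrow(co) < 2L) NA_real_ else co[2, 4],
    degenerate = degenerate
  )
  class(out) <- c("consistency_fit", class(out))
  out
}

#' Class a subject's peaks as shared or unique
#'
#' A subject peak is shared/unique iff it lies inside a group-wise cluster of
#' that class; peaks in neither stay unclassed.
#'
#' @param peakset a [peak_set()] (or integer vector) on the group template.
#' @param shared,unique `peak_clusters` tibbles of the two classes.
#' @return tibble with columns `vertex` and `class`
#'   (`"shared"`/`"unique"`/`"unclassed"`) plus `cluster_id` (NA when
#'   unclassed).
#' @export
individual_class_peaks <- function(peakset, shared, unique) {
  v <- as.integer(peakset)
  lookup <- function(cl) {
    if (nrow(cl) == 0L) {
      return(tibble::tibble(vertex = integer(), cluster_id = integer()))
    }
    tibble::tibble(
      vertex = unlist(cl$vertices),
      cluster_id = rep.int(cl$cluster_id, lengths(cl$vertices))
    )
  }
  sh <- lookup(shared); un <- lookup(unique)
  out <- tibble::tibble(vertex = v, class = "unclassed",
                        cluster_id = NA_integer_)
  ish <- match(v, sh$vertex)
  out$class[!is.na(ish)] <- "shared"
  out$cluster_id[!is.na(ish)] <- sh$cluster_id[ish[!is.na(ish)]]
  iun <- match(v, un$vertex)
  pick <- !is.na(iun) & out$class == "unclassed"
  out$class[pick] <- "unique"
  out$cluster_id[pick] <- un$cluster_id[iun[pick]]
  out
}
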