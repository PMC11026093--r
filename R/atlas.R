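#' Atlas region diversity around a peak
#'
#' Number of distinct nonzero atlas labels among the peak vertex and its
#' k-ring neighborhood (default 3-ring). Label 0 (unassigned) is excluded; a
#' peak whose whole neighborhood is unassigned yields 0 with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param labels a [label_map()] aligned to `mesh`.
#' @param peak vertex index.
#' @param ring neighborhood ring size (default 3).
#' @return non-negative integer count of distinct regions.
#' @export
region_diversity <- function(mesh, labels, peak, ring = 3) {
  stopifnot_mesh(mesh)
  check_aligned(labels, mesh, "labels")
  nb <- c(peak, k_ring(mesh, peak, ring))
  labs <- unique(as.integer(labels)[nb])
  labs <- labs[labs > 0L]
  if (length(labs) == 0L) {
    warning("peak ", peak, " and its ", ring, "-ring are entirely unlabeled")
    return(0L)
  }
  length(labs)
}

# vectorized diversity for many peaks on one atlas (shared ring matrix)
region_diversity_many <- function(mesh, labels, peaks, ring = 3) {
  rings <- k_ring_matrix(mesh, ring)
  labv <- as.integer(labels)
  vapply(as.integer(peaks), function(v) {
    nb <- c(v, rings@i[(rings@p[v] + 1L):rings@p[v + 1L]] + 1L)
    length(unique(labv[nb][labv[nb] > 0L]))
  }, 0L)
}

#' Shared vs unique region-diversity comparison across atlases
#'
#' For every subject, each classed peak's 3-ring region diversity is computed
#' per atlas, averaged per subject per class, and the two classes compared
#' with the pooled two-sample t-test. P-values are FDR-corrected across the
#' atlases tested in the run.
#'
#' @param classed_peaks list (one per subject) of tibbles from
#'   [individual_class_peaks()].
#' @param mesh a [surface_mesh()].
#' @param atlases named list of [label_map()] objects.
#' @param ring neighborhood ring size (default 3).
#' @return `feature_comparison` tibble, one row per atlas, with `p_fdr`.
#' @export
diversity_stats <- function(classed_peaks, mesh, atlases, ring = 3) {
  if (is.null(names(atlases))) names(atlases) <- paste0("atlas_", seq_along(atlases))
  rows <- purrr::imap(atlases, function(labels, aname) {
    ms <- vapply(classed_peaks, function(cp) {
      v <- cp$vertex[cp$class == "shared"]
      if (length(v) == 0L) NA_real_
      else mean(region_diversity_many(mesh, labels, v, ring))
    }, 0)
    mu <- vapply(classed_peaks, function(cp) {
      v <- cp$vertex[cp$class == "unique"]
      if (length(v) == 0L) NA_real_
      else mean(region_diversity_many(mesh, labels, v, ring))
    }, 0)
    compare_classes(ms, mu, feature_name = aname)
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_bh(out$p_value)
  class(out) <- c("feature_comparison", class(tibble::tibble()))
  out
}

#' Tally cluster centers per network and per order class
#'
#' Counts shared and unique cluster centers per atlas network, computes each
#' network's shared ratio after normalizing counts within class (so an
#' imbalance in the total number of shared vs unique clusters does not skew
#' the per-network ratio), and sums the counts over the lower-order and
#' higher-order network sets. Centers with label 0 are excluded.
#'
#' @param shared_centers,unique_centers integer vectors of cluster center
#'   vertices.
#' @param labels a [label_map()] whose table names the networks.
#' @param lower_set,higher_set character vectors of network names forming the
#'   lower/higher-order partition. Defaults are the sensory/motor vs
#'   associative split of the 12-network Cole-Anticevic partition.
#' @param region_area optional named numeric vector (by network name) of
#'   regional surface areas for per-area normalized counts.
#' @return list of class `network_tally` with `by_network` (tibble: network,
#'   order, n_shared, n_unique, ratio_shared, plus area-normalized columns if
#'   requested) and `by_order` (tibble: order, class totals).
#' @export
network_tally <- function(shared_centers, unique_centers, labels,
                          lower_set = c("V1", "V2", "Aud", "SMN", "PMN",
                                        "VMN", "OAN"),
                          higher_set = c("CON", "DAN", "Lan", "FPN", "DMN"),
                          region_area = NULL) {
  table <- attr(labels, "table")
  nets <- unname(table)
  uncovered <- setdiff(nets, c(lower_set, higher_set))
  if (length(uncovered) > 0L) {
    stop("networks not covered by lower/higher sets: ",
         paste(uncovered, collapse = ", "))
  }
  name_of <- function(centers) {
    lab <- as.integer(labels)[as.integer(centers)]
    if (any(lab == 0L)) {
      warning(sum(lab == 0L), " cluster centers are unlabeled; excluded")
    }
    table[as.character(lab[lab > 0L])]
  }
  sh <- name_of(shared_centers)
  un <- name_of(unique_centers)
  nets_in_order <- c(lower_set[lower_set %in% nets],
                     higher_set[higher_set %in% nets])
  by_network <- tibble::tibble(
    network = nets_in_order,
    order = ifelse(nets_in_order %in% lower_set, "lower", "higher"),
    n_shared = as.integer(table(factor(sh, levels = nets_in_order))),
    n_unique = as.integer(table(factor(un, levels = nets_in_order)))
  )
  # within-class normalized proportions, then the shared share per network
  ps <- by_network$n_shared / max(1L, length(sh))
  pu <- by_network$n_unique / max(1L, length(un))
  by_network$prop_shared <- ps
  by_network$prop_unique <- pu
  by_network$ratio_shared <- ifelse(ps + pu > 0, ps / (ps + pu), NA_real_)
  if (!is.null(region_area)) {
    ar <- region_area[by_network$network]
    by_network$shared_per_area <- by_network$n_shared / ar
    by_network$unique_per_area <- by_network$n_unique / ar
  }
  by_order <- by_network |>
    dplyr::group_by(.data$order) |>
    dplyr::summarise(n_shared = sum(.data$n_shared),
                     n_unique = sum(.data$n_unique), .groups = "drop")
  structure(list(by_network = by_network, by_order = by_order),
            class = "network_tally")
}

#' @export
print.network_tally <- function(x, ...) {
  cat("network_tally:\n")
  print(x$by_order)
  invisible(x)
}
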