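#' Published reference tallies of human and macaque gyral peak clusters
#'
#' Hemisphere-wise counts of group-wise gyral peak clusters reported for the
#' human and macaque cortex, split into species-shared and species-unique
#' classes, together with the lower-/higher-order network tallies of the
#' shared and unique cluster centers under the 12-network Cole-Anticevic
#' partition. Shipped so that the internal arithmetic of the reported tallies
#' (class counts summing to totals, network tallies conserving class totals)
#' can be checked mechanically.
#'
#' @return A list with two tibbles: `clusters` (species, hemisphere, total,
#'   shared, unique) and `networks` (species, order, shared, unique).
#' @examples
#' ref <- reference_cluster_counts()
#' with(ref$clusters, all(shared + unique == total))
#' @export
reference_cluster_counts <- function() {
  clusters <- tibble::tribble(
    ~species,  ~hemisphere, ~total, ~shared, ~unique,
    "human",   "L",         96L,    25L,     71L,
    "human",   "R",         96L,    26L,     70L,
    "macaque", "L",         42L,    25L,     17L,
    "macaque", "R",         43L,    26L,     17L
  )
  networks <- tibble::tribble(
    ~species,  ~order,   ~shared, ~unique,
    "human",   "lower",  33L,     37L,
    "human",   "higher", 18L,     104L,
    "macaque", "lower",  29L,     14L,
    "macaque", "higher", 22L,     20L
  )
  list(clusters = clusters, networks = networks)
}
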