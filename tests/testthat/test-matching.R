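make_clusters <- function(mesh, centers, radius_rings = 2, species = "x",
                          masses = NULL) {
  rows <- lapply(seq_along(centers), function(i) {
    verts <- if (radius_rings == 0) centers[i] else
      sort(c(centers[i], k_ring(mesh, centers[i], radius_rings)))
    tibble::tibble(cluster_id = i, center = centers[i],
                   mass = if (is.null(masses)) length(verts) else masses[i],
                   n_vertices = length(verts), vertices = list(verts))
  })
  peak_clusters(dplyr::bind_rows(rows), species = species, n_subjects = 20)
}

test_that("map_cluster: identity, collapse, permutation", {
  idmap <- correspondence_map(1:50, n_target = 50)
  expect_identical(map_cluster(c(3L, 9L, 20L), idmap), c(3L, 9L, 20L))
  twoto1 <- correspondence_map(rep(1:25, each = 2), n_target = 25)
  expect_lte(length(map_cluster(c(1, 2, 3, 4), twoto1)), 4)
  expect_identical(map_cluster(c(1, 2, 3, 4), twoto1), c(1L, 2L))
  set.seed(5)
  perm <- correspondence_map(sample(50), n_target = 50)
  cl <- c(4L, 17L, 33L, 41L)
  got <- map_cluster(cl, perm)
  expect_identical(got, sort(unique(vapply(cl, function(v) perm[v], 0L))))
  expect_length(got, length(cl))
})

test_that("dice matches hand values and rejects two empty sets", {
  expect_equal(dice(1:5, 1:5), 1)
  expect_equal(dice(1:3, 4:5), 0)
  expect_equal(dice(c(1, 2, 3), c(3, 4)), 0.4)
  expect_error(dice(integer(), integer()), "undefined")
})

test_that("match criteria: overlap qualifies regardless of distance, and 7 mm separates", {
  ico <- fixture_icosphere(3, radius = 40)
  # two clusters sharing one vertex but with distant centers
  a <- 1L
  ring_a <- k_ring(ico, a, 3)
  far <- ring_a[which.max(geodesic_distances(ico, a, ring_a))]
  ca <- make_clusters(ico, a, 3, species = "human")
  cb <- make_clusters(ico, far, 3, species = "macaque")
  stopifnot(length(intersect(ca$vertices[[1]], cb$vertices[[1]])) > 0)
  m1 <- match_shared(ca, cb, ico, d_max = 1e-6)  # distance can never fire
  expect_equal(nrow(m1$matches), 1)
  expect_identical(m1$matches$criterion_met, "dice")

  # disjoint clusters, centers ~5.2 mm apart -> matched by distance;
  # centers >> 7 mm apart -> unmatched
  d1 <- geodesic_distances(ico, a)[1, ]
  near <- which(d1 > 4.5 & d1 < 6.5)[1]
  ca1 <- make_clusters(ico, a, 0, species = "human")
  cb1 <- make_clusters(ico, near, 0, species = "macaque")
  m2 <- match_shared(ca1, cb1, ico, d_max = 7)
  expect_equal(nrow(m2$matches), 1)
  expect_identical(m2$matches$criterion_met, "distance")
  faraway <- which(d1 > 10 & d1 < 15)[1]
  m3 <- match_shared(ca1, make_clusters(ico, faraway, 0, species = "macaque"),
                     ico, d_max = 7)
  expect_equal(nrow(m3$matches), 0)
  expect_equal(nrow(m3$unique_a), 1)
  expect_equal(nrow(m3$unique_b), 1)
})

test_that("greedy matching equals the exhaustive oracle on planted candidate sets", {
  ico <- fixture_icosphere(3, radius = 40)
  set.seed(77)
  # well-separated candidate center pool so cluster sets stay disjoint
  vdir <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  pool <- apply(gyralpeaks:::dodecahedron_directions(), 1,
                function(u) which.max(vdir %*% u))
  n_ok <- 0
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    centers_a <- sample(pool, k)
    # b-clusters jittered near a subset of a's centers, plus extras
    keep <- sample(k, sample(2:k, 1))
    centers_b <- vapply(centers_a[keep], function(v) {
      nb <- k_ring(ico, v, 1)
      nb[sample.int(length(nb), 1)]
    }, 0L)
    ca <- make_clusters(ico, centers_a, 2, species = "human")
    cb <- make_clusters(ico, centers_b, 1, species = "macaque")
    got <- match_shared(ca, cb, ico, d_max = 7)
    cand <- tidyr::expand_grid(ai = seq_len(k), bi = seq_along(centers_b))
    cand$dice <- mapply(function(i, j) dice(ca$vertices[[i]], cb$vertices[[j]]),
                        cand$ai, cand$bi)
    cand$dist <- geodesic_distances(ico, centers_a, centers_b)[
      cbind(cand$ai, cand$bi)]
    cand <- cand[cand$dice > 0 | cand$dist < 7, ]
    best <- exhaustive_match_oracle(cand, k, length(centers_b))
    expect_equal(nrow(got$matches), best$count, info = paste("rep", rep))
    expect_equal(sum(got$matches$dice), best$dice, tolerance = 1e-9,
                 info = paste("rep", rep))
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 25)
})

test_that("shared and unique clusters partition each input set", {
  ico <- fixture_icosphere(3, radius = 40)
  set.seed(3)
  ca <- make_clusters(ico, sample(n_vertices(ico), 5), 2, species = "human")
  cb <- make_clusters(ico, sample(n_vertices(ico), 4), 2, species = "macaque")
  m <- match_shared(ca, cb, ico)
  expect_setequal(c(m$shared_a$cluster_id, m$unique_a$cluster_id),
                  ca$cluster_id)
  expect_setequal(c(m$shared_b$cluster_id, m$unique_b$cluster_id),
                  cb$cluster_id)
  # symmetry under swapping the species arguments
  m_swap <- match_shared(cb, ca, ico)
  expect_equal(nrow(m_swap$matches), nrow(m$matches))
  expect_setequal(paste(m_swap$matches$cluster_b_id, m_swap$matches$cluster_a_id),
                  paste(m$matches$cluster_a_id, m$matches$cluster_b_id))
})

test_that("hemisphere mismatch is an error", {
  ico <- fixture_icosphere(2)
  ca <- make_clusters(ico, 1L, 1)
  cb <- make_clusters(ico, 5L, 1)
  attr(cb, "hemisphere") <- "R"
  expect_error(match_shared(ca, cb, ico), "hemispheres")
})

test_that("consistency is summed count over the cluster per subject", {
  cnt <- scalar_map(c(2, 0, 3, 0, 15), "count", n_subjects = 20)
  expect_equal(consistency(c(1, 3), cnt), 5 / 20)
  expect_equal(consistency(integer(), cnt), 0)
  expect_error(consistency(1, scalar_map(1:5, "count")), "positive")
  # every subject peaking once inside the cluster -> 1.0
  expect_equal(consistency(5, scalar_map(c(0, 0, 0, 0, 20), "count",
                                         n_subjects = 20)), 1)
  # incidence-table oracle
  set.seed(8)
  inc <- matrix(rbinom(20 * 30, 1, 0.2), 20, 30)
  cmap <- scalar_map(colSums(inc), "count", n_subjects = 20)
  cl <- c(2, 9, 17, 25)
  expect_equal(consistency(cl, cmap), sum(inc[, cl]) / 20)
})

test_that("consistency regression recovers collinear and planted slopes", {
  fit <- consistency_regression(1:5, 2 * (1:5) + 1)
  expect_equal(fit$pcc, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  const <- consistency_regression(1:5, rep(3, 5))
  expect_true(const$degenerate)
  expect_equal(const$slope, 0)
  expect_true(is.na(const$pcc))
  expect_error(consistency_regression(1:2, 1:2), "at least 3")
  # planted slope with noise vs the closed-form normal-equations oracle
  set.seed(14)
  x <- runif(25, 0.5, 1.5)
  y <- 0.5 * x + rnorm(25, sd = 0.1)
  fit2 <- consistency_regression(x, y)
  orc <- ols_oracle(x, y)
  expect_equal(fit2$slope, orc$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(fit2$r_squared, orc$r_squared, tolerance = 1e-10)
  expect_equal(fit2$p_value, orc$p_slope, tolerance = 1e-10)
  se <- sqrt(sum((y - fit2$intercept - fit2$slope * x)^2) / 23 /
               sum((x - mean(x))^2))
  expect_lt(abs(fit2$slope - 0.5), qt(0.975, 23) * se)
})

test_that("individual peaks are classed by cluster membership", {
  ico <- fixture_icosphere(2)
  shared <- make_clusters(ico, c(1L), 1, species = "s")
  uniq <- make_clusters(ico, c(50L), 1, species = "s")
  # disjoint from all clusters -> unclassed
  out <- individual_class_peaks(peak_set(c(100L, 120L)), shared, uniq)
  expect_true(all(out$class == "unclassed"))
  # subset of the shared cluster -> all shared
  inside <- shared$vertices[[1]][1:3]
  out2 <- individual_class_peaks(peak_set(inside), shared, uniq)
  expect_true(all(out2$class == "shared"))
  # random peaks vs a set-intersection oracle
  set.seed(6)
  pk <- sample(n_vertices(ico), 40)
  out3 <- individual_class_peaks(peak_set(pk), shared, uniq)
  pk_sorted <- sort(pk)
  expect_identical(out3$vertex[out3$class == "shared"],
                   pk_sorted[pk_sorted %in% shared$vertices[[1]]])
  expect_identical(out3$vertex[out3$class == "unique"],
                   pk_sorted[pk_sorted %in% uniq$vertices[[1]] &
                               !pk_sorted %in% shared$vertices[[1]]])
})
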