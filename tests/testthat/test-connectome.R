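test_that("parcellation edge cases: singletons and one patch", {
  tet <- tetrahedron()
  p1 <- patch_parcellate(tet, 4, seed = 1)
  expect_setequal(as.integer(p1), 1:4)
  pall <- patch_parcellate(tet, 1, seed = 1)
  expect_true(all(as.integer(pall) == 1L))
  expect_error(patch_parcellate(tet, 5, seed = 1), "exceed")
})

test_that("icosphere parcellation is balanced, contiguous, deterministic", {
  ico <- fixture_icosphere(3, radius = 10)
  p <- patch_parcellate(ico, 12, seed = 7)
  sizes <- table(as.integer(p))
  expect_length(sizes, 12)
  n_per <- n_vertices(ico) / 12
  expect_true(all(sizes >= 0.5 * n_per & sizes <= 1.5 * n_per))
  # every patch is edge-connected: oracle via component search on the patch
  ed <- mesh_edges(ico)
  for (k in 1:12) {
    verts <- which(as.integer(p) == k)
    sub <- ed[ed$i %in% verts & ed$j %in% verts, ]
    g <- igraph::graph_from_data_frame(sub[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = verts))
    expect_equal(igraph::components(g)$no, 1, info = paste("patch", k))
  }
  expect_identical(as.integer(patch_parcellate(ico, 12, seed = 7)),
                   as.integer(p))
})

test_that("fc_matrix: clipped identical series, null decay, exact atanh", {
  set.seed(10)
  base <- matrix(rnorm(5 * 100), 5, 100)
  base[2, ] <- base[1, ]                      # identical pair -> clipped
  g <- fc_matrix(base)
  expect_equal(g[1, 2], atanh(1 - 1e-7))
  expect_equal(diag(unclass(g)), rep(0, 5))
  # independent white noise, many timepoints -> small |z|
  set.seed(11)
  noise <- matrix(rnorm(8 * 1000), 8, 1000)
  gn <- fc_matrix(noise)
  off <- gn[upper.tri(gn)]
  expect_true(all(abs(off) < 0.2))
  # constructed series with exactly r = 0.5
  x <- rep(c(1, -1), 50)
  y <- rep(c(1, 1, -1, -1), 25)
  z <- 0.5 * x + sqrt(0.75) * y               # cor(x, z) = 0.5 exactly
  gz <- fc_matrix(rbind(x, z))
  expect_equal(gz[1, 2], 0.5493, tolerance = 1e-4)
  expect_equal(gz[1, 2], atanh(0.5), tolerance = 1e-12)
})

test_that("fc_matrix flags constant series and averages per patch", {
  ts <- rbind(rep(1, 50), matrix(rnorm(100), 2, 50))
  expect_warning(g <- fc_matrix(ts), "constant")
  expect_true(all(is.na(g[1, -1])))
  # vertex series + parcellation: entries equal correlations of patch means
  set.seed(3)
  vts <- matrix(rnorm(6 * 40), 6, 40)
  parc <- structure(c(1L, 1L, 2L, 2L, 3L, 3L), n_patches = 3L,
                    class = c("parcellation", "integer"))
  gp <- fc_matrix(vts, parc)
  m1 <- colMeans(vts[1:2, ]); m2 <- colMeans(vts[3:4, ])
  expect_equal(gp[1, 2], atanh(cor(m1, m2)), tolerance = 1e-12)
})

test_that("sc_matrix tallies endpoint pairs per patch pair", {
  parc <- structure(rep(1:4, each = 5), n_patches = 4L,
                    class = c("parcellation", "integer"))
  empty <- sc_matrix(matrix(integer(), 0, 2), parc)
  expect_true(all(empty == 0))
  ten <- sc_matrix(matrix(rep(c(2L, 7L), 10), ncol = 2, byrow = TRUE), parc)
  expect_equal(ten[1, 2], 10)
  expect_equal(ten[2, 1], 10)
  expect_equal(sum(ten), 20)
  set.seed(4)
  ep <- cbind(sample(20, 1000, TRUE), sample(20, 1000, TRUE))
  got <- sc_matrix(ep, parc)
  want <- matrix(0, 4, 4)
  for (r in seq_len(1000)) {
    pi_ <- parc[ep[r, 1]]; pj <- parc[ep[r, 2]]
    if (pi_ != pj) {
      want[pi_, pj] <- want[pi_, pj] + 1
      want[pj, pi_] <- want[pj, pi_] + 1
    }
  }
  expect_equal(unclass(got)[1:4, 1:4], want, ignore_attr = TRUE)
})

test_that("group_average is the elementwise mean", {
  g1 <- random_connectivity_graph(6, seed = 1)
  expect_equal(unclass(group_average(list(g1))), unclass(g1),
               ignore_attr = TRUE)
  g3 <- connectivity_graph(3 * unclass(g1), kind = "functional")
  expect_equal(unclass(group_average(list(g1, g3))), 2 * unclass(g1),
               ignore_attr = TRUE)
  gs <- lapply(1:10, random_connectivity_graph, n = 6)
  avg <- group_average(gs)
  want <- Reduce(`+`, lapply(gs, unclass)) / 10
  expect_equal(unclass(avg), want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(group_average(list(g1, random_connectivity_graph(5, 2))),
               "shape")
})

test_that("threshold_top keeps the per-row top fraction then symmetrizes", {
  set.seed(2)
  w <- matrix(runif(11 * 11), 11, 11); w <- (w + t(w)) / 2; diag(w) <- 0
  g <- connectivity_graph(w, "functional")
  thr <- threshold_top(g, 0.1)               # ceil(0.1 * 10) = 1 per row
  pre_rows <- apply(unclass(g), 1, function(r) which.max(r))
  for (i in 1:11) expect_true(thr[i, pre_rows[i]] > 0)
  expect_true(all(thr == t(unclass(thr))))
  expect_error(threshold_top(g, 0), "fraction")
  # fraction = 1 keeps everything
  expect_equal(unclass(threshold_top(g, 1)), w, ignore_attr = TRUE)
})

test_that("threshold survivors match a sort oracle; idempotent; bounded density", {
  set.seed(13)
  n <- 50
  w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
  g <- connectivity_graph(w, "functional")
  thr <- threshold_top(g, 0.1)
  keep_k <- ceiling(0.1 * (n - 1))
  rowwise <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(-w[i, -i])
    cols <- setdiff(seq_len(n), i)[ord][seq_len(keep_k)]
    rowwise[i, cols] <- w[i, cols]
  }
  expect_equal(unclass(thr), pmax(rowwise, t(rowwise)), ignore_attr = TRUE)
  expect_equal(unclass(threshold_top(thr, 0.1)), unclass(thr),
               ignore_attr = TRUE)
  density <- mean(thr[upper.tri(thr)] > 0)
  expect_lte(density, 2 * 0.1 * n / (n - 1))
})

test_that("node metrics match closed forms on canonical graphs", {
  n <- 6
  w <- matrix(1, n, n); diag(w) <- 0
  m <- node_metrics(connectivity_graph(w, "functional", thresholded = TRUE))
  expect_equal(m$degree, rep(n - 1, n))
  expect_equal(m$strength, rep(n - 1, n))
  expect_equal(m$clustering_coef, rep(1, n), tolerance = 1e-12)
  expect_equal(m$betweenness, rep(0, n), tolerance = 1e-12)
  expect_equal(m$efficiency, rep(1, n), tolerance = 1e-12)
  # binary path a-b-c-d: betweenness(b) = 2 ({a,c}, {a,d})
  wp <- matrix(0, 4, 4)
  wp[cbind(1:3, 2:4)] <- 1; wp <- wp + t(wp)
  mp <- node_metrics(connectivity_graph(wp, "functional", thresholded = TRUE))
  expect_equal(mp$betweenness, c(0, 2, 2, 0))
  expect_equal(mp$degree, c(1, 2, 2, 1))
})

test_that("all five node metrics equal the brute-force oracle on random graphs", {
  for (seed in 1:12) {
    n <- sample(5:8, 1)
    g <- random_connectivity_graph(n, seed = seed, density = 0.6)
    w <- unclass(g) / max(unclass(g))      # rescale so efficiency is in [0,1]
    g <- connectivity_graph(w, "functional", thresholded = TRUE)
    got <- node_metrics(g)
    orc <- node_metrics_oracle(w)
    for (metric in c("degree", "strength", "clustering_coef", "betweenness",
                     "efficiency")) {
      expect_equal(got[[metric]], orc[[metric]], tolerance = 1e-9,
                   info = paste(metric, "seed", seed))
    }
    expect_true(all(got$efficiency >= 0 & got$efficiency <= 1 + 1e-12))
    expect_true(all(got$degree <= n - 1))
  }
})

test_that("peak node properties equal a lookup oracle and keep directions", {
  parc <- structure(rep(1:5, each = 4), n_patches = 5L,
                    class = c("parcellation", "integer"))
  metrics <- tibble::tibble(node = 1:5, degree = c(10, 2, 3, 1, 8),
                            strength = c(5, 1, 2, 0.5, 4))
  set.seed(20)
  classed <- lapply(1:8, function(s) {
    tibble::tibble(
      vertex = c(sample(1:4, 2), sample(13:16, 1), sample(17:20, 1)),
      class = c("shared", "shared", "unique", "unique"),  # patches 1 / 4+5
      cluster_id = c(1L, 1L, 2L, 3L))
  })
  out <- peak_node_props(classed, parc, metrics)
  expect_identical(out$feature, c("degree", "strength"))
  expect_equal(out$mean_shared[1], 10)    # all shared peaks in patch 1
  expect_equal(out$mean_unique[1], 4.5)   # unique split over patches 4 and 5
  expect_gt(out$t_value[1], 0)            # planted hub direction
  # dropped patch -> excluded with a warning
  metrics2 <- metrics[-5, ]
  expect_warning(peak_node_props(classed[1:3], parc, metrics2), "dropped")
})
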