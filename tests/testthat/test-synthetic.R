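test_that("noiseless, jitter-free subjects reproduce the planted loci exactly", {
  des <- small_design(seed = 2, noise_sd = 0, jitter_rings = 0L,
                      presence = c(shared = 1, unique = 1), n_subjects = 3L)
  for (sp in c("human", "macaque")) {
    spd <- make_species(des, sp)
    k <- if (sp == "human") 4 else 3
    for (subj in spd$subjects) {
      p <- detect_peaks(spd$mesh, subj$sulc, k = k)
      expect_setequal(as.integer(p), spd$loci$vertex)
    }
  }
})

test_that("generators are pure functions of the design seed", {
  d1 <- small_design(seed = 5)
  d2 <- small_design(seed = 5)
  h1 <- make_species(d1, "human")
  h2 <- make_species(d2, "human")
  expect_identical(h1$loci, h2$loci)
  expect_identical(h1$subjects, h2$subjects)
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  g1 <- make_gene_table(d1)
  g2 <- make_gene_table(d2)
  expect_identical(g1$expression, g2$expression)
  d3 <- small_design(seed = 6)
  expect_false(identical(make_species(d3, "human")$subjects[[1]]$sulc,
                         h1$subjects[[1]]$sulc))
})

test_that("planted feature contrasts follow the anatomical directions", {
  des <- small_design(seed = 3)
  hum <- make_species(des, "human")
  sh <- hum$loci$vertex[hum$loci$class == "shared"]
  un <- hum$loci$vertex[hum$loci$class == "unique"]
  s1 <- hum$subjects[[1]]
  expect_gt(mean(abs(s1$sulc[sh])), mean(abs(s1$sulc[un])))
  expect_lt(mean(s1$curv[sh]), mean(s1$curv[un]))
  expect_gt(mean(s1$area[sh]), mean(s1$area[un]))
  expect_lt(mean(s1$thickness[sh]), mean(s1$thickness[un]))
  expect_gt(mean(s1$myelin[sh]), mean(s1$myelin[un]))
  mac <- make_species(des, "macaque")
  expect_null(mac$subjects[[1]]$thickness)
  expect_null(mac$subjects[[1]]$myelin)
})

test_that("identity-geometry correspondence is the identity map", {
  des <- synthetic_design(seed = 4, rotation_deg = 0,
                          mesh_human = list(subdivisions = 3L, radius = 50),
                          mesh_macaque = list(subdivisions = 3L, radius = 50))
  mp <- make_correspondence(des, "macaque_to_human")
  expect_identical(as.integer(mp), seq_along(mp))
})

test_that("paired shared loci map within 7 mm; composition displacement small", {
  # the 7 mm pairing guarantee holds at the default template resolutions
  des <- synthetic_design(seed = 9, n_subjects = 1L)
  hum <- make_species(des, "human")
  mac <- make_species(des, "macaque")
  m2h <- make_correspondence(des, "macaque_to_human", source = mac,
                             target = hum)
  sh_h <- hum$loci$vertex[hum$loci$class == "shared"]
  sh_m <- mac$loci$vertex[mac$loci$class == "shared"]
  mapped <- as.integer(m2h)[sh_m]
  d <- diag(geodesic_distances(hum$mesh, mapped, sh_h))
  expect_true(all(d < 7))
  # unique loci images stay >= 3 x 7 mm from every opposite-species locus
  un_m_img <- as.integer(m2h)[mac$loci$vertex[mac$loci$class == "unique"]]
  dd <- geodesic_distances(hum$mesh, un_m_img, hum$loci$vertex)
  expect_true(all(dd > 21))
  # composing with the inverse map moves vertices at most ~2 edges
  h2m <- make_correspondence(des, "human_to_macaque", source = hum,
                             target = mac)
  roundtrip <- as.integer(m2h)[as.integer(h2m)]
  edge_len <- mean(mesh_edges(hum$mesh)$length)
  disp <- sqrt(rowSums((hum$mesh$vertices[roundtrip, ] -
                          hum$mesh$vertices)^2))
  expect_true(all(disp <= 2 * edge_len + 1e-9))
})

test_that("time series carry the designed community correlation structure", {
  des <- small_design(seed = 12)
  des$timeseries <- list(n_timepoints = 1000L, n_communities = 6L, rho = 0.8)
  parc <- structure(rep(1:30, each = 2), n_patches = 30L,
                    class = c("parcellation", "integer"))
  ts <- make_timeseries(des, parc, hub_patches = integer(), n_subjects = 1)
  x <- ts$series[[1]]
  cors <- cor(t(x))
  within <- cors[outer(ts$community, ts$community, "==") & upper.tri(cors)]
  between <- cors[outer(ts$community, ts$community, "!=") & upper.tri(cors)]
  expect_gt(mean(within), 0.6)
  expect_lt(mean(within), 0.9)
  expect_lt(abs(mean(between)), 0.1)
  # zero within-community correlation -> Fisher z near 0 everywhere
  des$timeseries$rho <- 0
  ts0 <- make_timeseries(des, parc, n_subjects = 1)
  z0 <- fc_matrix(ts0$series[[1]])
  expect_lt(max(abs(z0[upper.tri(z0)])), 0.2)
  # reproducibility
  ts_again <- make_timeseries(des, parc, n_subjects = 1)
  expect_identical(ts0$series, ts_again$series)
})

test_that("hub patches exceed the median thresholded degree and strength", {
  des <- small_design(seed = 13)
  parc <- structure(rep(1:40, each = 3), n_patches = 40L,
                    class = c("parcellation", "integer"))
  hubs <- c(4L, 19L, 33L)
  ts <- make_timeseries(des, parc, hub_patches = hubs, n_subjects = 8)
  fc <- threshold_top(group_average(lapply(ts$series, fc_matrix)), 0.10)
  nm <- node_metrics(fc)
  expect_true(all(nm$degree[hubs] > median(nm$degree[-hubs])))
  expect_true(all(nm$strength[hubs] > median(nm$strength[-hubs])))
})

test_that("gene tables plant the designed class shift", {
  des <- small_design(seed = 14)
  gt <- make_gene_table(des)
  expect_identical(dim(gt$expression),
                   c(74L, des$genes$n_genes))
  expect_length(gt$informative_genes, des$genes$n_informative)
  sh <- gt$region_class$class == "shared"
  un <- gt$region_class$class == "unique"
  inf_shift <- colMeans(gt$expression[sh, gt$informative_genes]) -
    colMeans(gt$expression[un, gt$informative_genes])
  expect_true(all(inf_shift > 1))    # planted d = 2 with sampling noise
  others <- setdiff(colnames(gt$expression), gt$informative_genes)
  null_shift <- colMeans(gt$expression[sh, others]) -
    colMeans(gt$expression[un, others])
  expect_lt(max(abs(null_shift)), 1.5)
})

test_that("single-region atlases give diversity 1 everywhere", {
  ico <- fixture_icosphere(2)
  one <- label_map(rep(1L, n_vertices(ico)))
  divs <- gyralpeaks:::region_diversity_many(ico, one,
                                             sample(n_vertices(ico), 10), 3)
  expect_true(all(divs == 1L))
})

test_that("planted atlas layouts put shared loci on boundaries", {
  des <- small_design(seed = 15)
  hum <- make_species(des, "human")
  atl <- make_atlases(des, hum$mesh, loci = hum$loci)
  labs <- atl[[paste0("atlas_", max(des$atlas_resolutions))]]
  sh <- hum$loci$vertex[hum$loci$class == "shared"]
  un <- hum$loci$vertex[hum$loci$class == "unique"]
  div_sh <- gyralpeaks:::region_diversity_many(hum$mesh, labs, sh, 3)
  div_un <- gyralpeaks:::region_diversity_many(hum$mesh, labs, un, 3)
  expect_true(all(div_sh >= 2))
  expect_gt(mean(div_sh), mean(div_un))
  expect_named(atl, c(paste0("atlas_", des$atlas_resolutions), "networks"))
  expect_length(unique(unname(attr(atl$networks, "table"))), 12)
})
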