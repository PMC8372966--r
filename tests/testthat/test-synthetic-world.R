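test_that("a world is a deterministic function of its configuration", {
  cfg <- world_config(n_species = 8, grid_rows = 15, grid_cols = 15,
                      points_per_species = c(5, 10), seed = 42)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$raster, w2$raster)
  expect_identical(w1$tree, w2$tree)
  expect_identical(w1$labels, w2$labels)
  expect_identical(w1$centers, w2$centers)
  expect_identical(w1$occurrences, w2$occurrences)
})

test_that("unsmoothed uncorrelated layers are empirically uncorrelated", {
  cfg <- world_config(n_species = 2, grid_rows = 100, grid_cols = 100,
                      smoothing_radius = 0,
                      layer_correlation = diag(12),
                      temp_lat_gradient = 0, seed = 3)
  r <- generate_climate_raster(cfg)
  X <- raster_values(r)
  X <- scale(X)
  cc <- stats::cor(X)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("imposed cross-layer correlation is recovered empirically", {
  R <- diag(12)
  R[1, 2] <- R[2, 1] <- 0.8   # BIO1 - BIO5
  cfg <- world_config(n_species = 2, grid_rows = 100, grid_cols = 100,
                      smoothing_radius = 0, layer_correlation = R,
                      temp_lat_gradient = 0, seed = 4)
  X <- raster_values(generate_climate_raster(cfg))
  expect_equal(stats::cor(X[, "BIO1"], X[, "BIO5"]), 0.8, tolerance = 0.05)
})

test_that("a non-PSD layer correlation is rejected", {
  R <- diag(12)
  R[1, 2] <- R[2, 1] <- 1.5
  expect_error(world_config(layer_correlation = R), "semi-definite")
})

test_that("annual temperature declines with absolute latitude", {
  cfg <- world_config(n_species = 2, grid_rows = 60, grid_cols = 60,
                      temp_lat_gradient = 10, smoothing_radius = 3,
                      seed = 5)
  r <- generate_climate_raster(cfg)
  rowmean <- rowMeans(r$values$BIO1)
  abslat <- abs(row_latitudes(r))
  expect_lt(stats::cor(rowmean, abslat, method = "spearman"), -0.9)
  expect_lt(stats::lm(rowmean ~ abslat)$coefficients[2], 0)
})

test_that("elevation is nonnegative and all twelve layers are present", {
  r <- generate_climate_raster(world_config(grid_rows = 20, grid_cols = 20,
                                            seed = 6))
  expect_named(r$values, climate_codes())
  expect_true(all(r$values$Elev >= 0))
})

test_that("the smallest chronogram has one node and equal tip paths", {
  tr <- simulate_chronogram(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(tr$Nnode, 1L)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1], d[2])
})

test_that("chronograms have the requested tip count and are ultrametric", {
  tr <- simulate_chronogram(277, birth_rate = 1, seed = 2)
  expect_equal(ape::Ntip(tr), 277L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_false(any(duplicated(tr$tip.label)))
  expect_error(simulate_chronogram(1), ">= 2")
})

test_that("mean tree height matches the pure-birth expectation", {
  n_rep <- 2000
  set.seed(7)
  heights <- vapply(seq_len(n_rep), function(i) {
    max(ape::node.depth.edgelength(simulate_chronogram(8, 1)))
  }, numeric(1))
  expected <- sum(1 / (2:8))  # exponential waits at rates 2..8
  se <- stats::sd(heights) / sqrt(n_rep)
  expect_lt(abs(mean(heights) - expected), 3 * se)
})

test_that("microhabitat evolution respects degenerate and extreme rates", {
  tr <- simulate_chronogram(20, seed = 8)
  lab0 <- assign_microhabitats(tr, 0, 0, root_state = "terrestrial",
                               seed = 1)
  expect_true(all(lab0 == "terrestrial"))
  lab1 <- assign_microhabitats(tr, 0, 0, root_state = "arboreal", seed = 1)
  expect_true(all(lab1 == "arboreal"))
  expect_error(assign_microhabitats(tr, -1, 1), ">= 0")

  # very fast equal rates: tips are independent coin flips
  set.seed(9)
  frac <- vapply(seq_len(500), function(i)
    mean(assign_microhabitats(tr, 500, 500) == "arboreal"), numeric(1))
  se <- stats::sd(frac) / sqrt(500)
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("strongly asymmetric loss keeps arboreality rare", {
  tr <- simulate_chronogram(20, seed = 10)
  set.seed(11)
  frac <- vapply(seq_len(500), function(i)
    mean(assign_microhabitats(tr, gain_rate = 0.2,
                              loss_rate = 23 * 0.2) == "arboreal"),
    numeric(1))
  expect_lt(mean(frac), 0.5)
})

test_that("degenerate Brownian diffusion returns the root value", {
  tr <- simulate_chronogram(6, seed = 12)
  lab <- stats::setNames(rep("terrestrial", 6), tr$tip.label)
  v <- evolve_niche_centers(tr, lab, bm_sigma = 0, arboreal_shift = 0,
                            root_value = 7, seed = 1)
  expect_true(all(v == 7))
})

test_that("the injected arboreal shift is recovered in group means", {
  tr <- simulate_chronogram(10, seed = 13)
  lab <- stats::setNames(rep(c("arboreal", "terrestrial"), each = 5),
                         tr$tip.label)
  shift <- c(2, -1, rep(0, 10))
  set.seed(14)
  diffs <- t(vapply(seq_len(1000), function(i) {
    v <- evolve_niche_centers(tr, lab, bm_sigma = 1,
                              arboreal_shift = shift)
    colMeans(v[lab == "arboreal", ]) - colMeans(v[lab == "terrestrial", ])
  }, numeric(12)))
  se <- apply(diffs, 2L, stats::sd) / sqrt(1000)
  expect_true(all(abs(colMeans(diffs) - shift) < 3 * se))
})

test_that("tip covariance under zero shift follows the tree", {
  tr <- simulate_chronogram(6, seed = 15)
  C <- phylo_covariance(tr)
  set.seed(16)
  tips <- t(vapply(seq_len(3000), function(i)
    evolve_niche_centers(tr, stats::setNames(rep("terrestrial", 6),
                                             tr$tip.label),
                         bm_sigma = 1)[, 1], numeric(6)))
  emp <- stats::cov(tips)
  expect_lt(max(abs(emp - C[colnames(emp), colnames(emp)])),
            0.15 * max(C))
})

test_that("occurrence sampling degenerates to the best pixel", {
  r <- toy_raster()
  center <- raster_values(r)[37, ]
  pts <- sample_occurrences(center, rep(1e-6, 12), r, 20, seed = 17)
  expect_equal(nrow(unique(pts)), 1L)
  got <- extract_climate(pts[1, ], r)
  expect_equal(unlist(got[climate_codes()]), center,
               ignore_attr = TRUE)
})

test_that("sampled climate concentrates on the center as breadth shrinks", {
  cfg <- world_config(n_species = 2, grid_rows = 30, grid_cols = 30,
                      seed = 18)
  r <- generate_climate_raster(cfg)
  X <- raster_values(r)
  center <- X[200, ]
  spread <- apply(X, 2L, stats::sd)
  err <- vapply(c(4, 1, 0.25), function(f) {
    pts <- sample_occurrences(center, f * spread, r, 5000, seed = 19)
    got <- extract_climate(pts, r)
    mean(abs(colMeans(as.matrix(got[climate_codes()])) - center) / spread)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_silent(sample_occurrences(center, spread, r, 3, seed = 20))
})

test_that("occurrences generated by a world stay inside the raster", {
  cfg <- world_config(n_species = 6, grid_rows = 12, grid_cols = 12,
                      points_per_species = c(3, 8), seed = 21)
  w <- simulate_world(cfg)
  idx <- pixel_index(w$raster, w$occurrences$longitude,
                     w$occurrences$latitude)
  expect_true(all(idx$inside))
})
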