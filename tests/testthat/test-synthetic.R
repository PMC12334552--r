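test_that("landscapes are deterministic per seed and standardized", {
  g <- grid_spec(30, 30, 0.05, lat_top = -15, lon_left = 44)
  a <- make_landscape(g, 3, 2, seed = 5)
  b <- make_landscape(g, 3, 2, seed = 5)
  expect_identical(a, b)
  c <- make_landscape(g, 3, 2, seed = 6)
  expect_false(identical(a$layers[[1]]$values, c$layers[[1]]$values))
  for (l in a$layers) {
    expect_equal(mean(l$values), 0, tolerance = 1e-12)
    expect_equal(sd(l$values), 1, tolerance = 1e-12)
  }
})

test_that("autocorrelation range controls neighbor correlation", {
  g <- grid_spec(100, 100, 0.05, lat_top = -15, lon_left = 44)
  white <- make_landscape(g, 1, 0, seed = 9)
  expect_lt(abs(neighbor_correlation(white$layers[[1]])), 0.05)
  smooth <- make_landscape(g, 1, 5, seed = 9)
  expect_gt(neighbor_correlation(smooth$layers[[1]]), 0.5)
})

test_that("climate perturbation shifts named layers additively", {
  g <- grid_spec(10, 10, 0.5, lat_top = 0)
  st <- make_landscape(g, 2, 1, seed = 3, layer_names = c("bio12", "bio15"))
  same <- perturb_climate(st, c(bio12 = 0), "ssp245")
  expect_identical(same$layers$bio12$values, st$layers$bio12$values)
  expect_identical(same$scenario_id, "ssp245")

  up <- perturb_climate(st, c(bio12 = 1), "ssp585")
  expect_equal(mean(up$layers$bio12$values) - mean(st$layers$bio12$values), 1)
  expect_identical(up$layers$bio15$values, st$layers$bio15$values)

  twice <- perturb_climate(perturb_climate(st, c(bio12 = 0.5), "a"),
                           c(bio12 = 0.5), "b")
  once <- perturb_climate(st, c(bio12 = 1), "b")
  expect_equal(twice$layers$bio12$values, once$layers$bio12$values)

  expect_error(perturb_climate(st, c(bio99 = 1), "x"), "unknown layer")
})

test_that("true suitability is a rescaled product of Gaussian responses", {
  g <- grid_spec(1, 5, 1, lat_top = 0)
  st <- env_stack(list(env_layer("a", c(-2, -1, 0, 1, 2), g)))
  vs <- virtual_species_spec("v", c(a = 0), c(a = 0.7))
  s <- true_suitability(vs, st)
  expect_equal(max(s$values), 1)            # optimum cell rescales to 1
  expect_identical(which.max(s$values), 3L)
  # ordering equals ordering of -|x - mu| for a one-layer species
  expect_identical(order(s$values), order(-abs(c(-2, -1, 0, 1, 2))))
  # very broad niche tends to uniform suitability
  vs_wide <- virtual_species_spec("w", c(a = 0), c(a = 1e6))
  expect_equal(diff(range(true_suitability(vs_wide, st)$values)), 0,
               tolerance = 1e-9)
})

test_that("presence sampling is suitability-biased and seed-stable", {
  g <- grid_spec(20, 20, 0.1, lat_top = 0)
  st <- make_landscape(g, 1, 2, seed = 21, layer_names = "a")
  vs <- virtual_species_spec("v", c(a = 0), c(a = 0.5))
  truth <- true_suitability(vs, st)

  expect_identical(nrow(sample_presences(truth, 0)), 0L)
  expect_identical(sample_presences(truth, 50, seed = 4),
                   sample_presences(truth, 50, seed = 4))

  # all mass on one cell -> every record in that cell
  conc <- suitability_map("v", "current", c(1, rep(0, 399)), g)
  occ <- sample_presences(conc, 25, seed = 1)
  expect_true(all(point_to_cell(occ$lon, occ$lat, g)$cell == 1L))

  # size-biased draw: mean suitability at sampled cells beats the grid mean
  occ2 <- sample_presences(truth, 1000, seed = 2)
  cells <- point_to_cell(occ2$lon, occ2$lat, g)$cell
  expect_gt(mean(truth$values[cells]), mean(truth$values))

  zero <- suitability_map("v", "current", rep(0, 400), g)
  expect_error(sample_presences(zero, 5), "all-zero")
})

test_that("pa mask generation hits the coverage target", {
  g <- grid_spec(100, 100, 0.05, lat_top = 0)
  expect_false(any(make_pa_mask(g, 0)$covered))
  expect_true(all(make_pa_mask(g, 1)$covered))
  m <- make_pa_mask(g, 0.3, n_blocks = 10, seed = 8)
  expect_gte(mean(m$covered), 0.28)
  expect_lte(mean(m$covered), 0.32)
  expect_identical(m, make_pa_mask(g, 0.3, n_blocks = 10, seed = 8))
  expect_error(make_pa_mask(g, 0.5, n_blocks = 0), "n_blocks")
})

test_that("with_seed restores the caller's RNG state", {
  set.seed(123)
  first <- runif(1)
  set.seed(123)
  invisible(with_seed(999, runif(10)))
  expect_identical(runif(1), first)
})
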