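test_that("cell areas follow the spherical-zone formula", {
  # 2.5-arc-minute cell centered on the equator: R^2 * dlam * (sin n - sin s)
  g <- grid_spec(1, 1, 2.5 / 60, lat_top = (2.5 / 60) / 2)
  dlam <- (2.5 / 60) * pi / 180
  expected <- EARTH_RADIUS_KM^2 * dlam *
    (sin(dlam / 2) - sin(-dlam / 2))
  expect_equal(cell_area_km2(0, g), expected, tolerance = 1e-12)
  expect_equal(expected, 21.4, tolerance = 5e-3)

  # all cells in one row have the same area; rows nearer a pole are smaller
  g2 <- grid_spec(10, 12, 1, lat_top = 60)
  a <- matrix(grid_cell_areas(g2), nrow = 10, byrow = TRUE)
  expect_true(all(apply(a, 1, function(r) diff(range(r)) == 0)))
  expect_true(all(diff(a[, 1]) > 0))  # moving south toward the equator here

  expect_error(cell_area_km2(10, g2), "outside")
})

test_that("a full global grid sums to the sphere surface", {
  g <- grid_spec(180, 360, 1, lat_top = 90, lon_left = -180)
  expect_equal(sum(grid_cell_areas(g)), 4 * pi * EARTH_RADIUS_KM^2,
               tolerance = 1e-6)
})

test_that("masked_area_km2 is additive and conformance-checked", {
  g <- grid_spec(8, 9, 0.5, lat_top = -10, lon_left = 20)
  n <- 8 * 9
  expect_identical(masked_area_km2(rep(FALSE, n), g), 0)
  set.seed(7)
  for (i in 1:20) {
    m <- runif(n) < 0.3
    expect_equal(masked_area_km2(m, g) + masked_area_km2(!m, g),
                 sum(grid_cell_areas(g)))
    m2 <- runif(n) < 0.3
    expect_equal(masked_area_km2(m | m2, g) + masked_area_km2(m & m2, g),
                 masked_area_km2(m, g) + masked_area_km2(m2, g))
  }
  expect_error(masked_area_km2(rep(TRUE, 5), g), "match")
})

test_that("point-to-cell assignment uses half-open cell intervals", {
  g <- grid_spec(4, 4, 1, lat_top = 0, lon_left = 10)
  # west edge belongs to the cell, north edge belongs to the cell
  expect_identical(point_to_cell(10, -1, g)$row, 1L)   # north edge of row 1
  expect_identical(point_to_cell(10, -1, g)$col, 0L)
  expect_identical(point_to_cell(11, -0.5, g)$col, 1L) # west edge of col 1
  # grid's own northern edge is inclusive
  expect_identical(point_to_cell(10.5, 0, g)$row, 0L)
  # outside
  expect_true(is.na(point_to_cell(9.99, -1, g)$cell))
  expect_true(is.na(point_to_cell(14, -1, g)$cell))
  # round trip through cell centers
  ctr <- cell_center(1:16, g)
  expect_identical(point_to_cell(ctr$lon, ctr$lat, g)$cell, 1:16)
})

make_stack_from_vectors <- function(...) {
  vecs <- list(...)
  n <- length(vecs[[1]])
  g <- grid_spec(n %/% 5, 5, 1, lat_top = 0)
  env_stack(lapply(names(vecs), function(nm) env_layer(nm, vecs[[nm]], g)))
}

test_that("collinearity filter drops the lower-priority member of hot pairs", {
  set.seed(2)
  n <- 500
  A <- rnorm(n)
  B <- 0.9 * A + sqrt(1 - 0.81) * rnorm(n)   # r(A,B) ~ 0.9
  C <- 0.22 * A + rnorm(n)                   # r(A,C) ~ 0.2
  st <- make_stack_from_vectors(A = A, B = B, C = C)
  expect_identical(filter_collinear(st, 0.75), c("A", "C"))
  # priority reversal keeps B instead
  expect_identical(filter_collinear(st, 0.75, priority = c("B", "C", "A")),
                   c("B", "C"))
  # identical layers: exactly one survives, the higher-priority one
  st2 <- make_stack_from_vectors(A = A, A2 = A)
  expect_identical(filter_collinear(st2, 0.75), "A")
  # independent noise layers both survive
  st3 <- make_stack_from_vectors(X = rnorm(n), Y = rnorm(n))
  expect_identical(filter_collinear(st3, 0.75), c("X", "Y"))
  # idempotence: filtering a retained set changes nothing
  kept <- filter_collinear(st, 0.75)
  st_kept <- env_stack(st$layers[kept])
  expect_identical(filter_collinear(st_kept, 0.75), kept)
})

test_that("zero-variance layers warn and are treated as uncorrelated", {
  set.seed(3)
  st <- make_stack_from_vectors(A = rnorm(100), Z = rep(1, 100))
  expect_warning(kept <- filter_collinear(st, 0.75), "zero-variance")
  expect_identical(kept, c("A", "Z"))
})

test_that("jenks_breaks matches brute-force partition enumeration", {
  expect_identical(jenks_breaks(c(5, 1, 9), 1), numeric(0))
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), 2), 6.5)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")

  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    k <- sample(2:4, 1)
    v <- round(runif(n, 0, 100), 2)
    if (length(unique(v)) < k) next
    br <- jenks_breaks(v, k)
    expect_identical(jenks_classify(sort(v), br), brute_jenks_classes(v, k))
  }
})
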