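test_that("EOO is a projected convex-hull area", {
  expect_identical(eoo_km2(data.frame(lon = 5, lat = 5)), 0)
  expect_identical(eoo_km2(data.frame(lon = c(5, 6), lat = c(5, 5))), 0)
  sq <- data.frame(lon = c(0, 0, 1, 1), lat = c(0, 1, 0, 1))
  expect_equal(eoo_km2(sq), 111.195^2, tolerance = 0.01)
  # point-order and duplication invariance
  shuf <- sq[c(3, 1, 4, 2), ]
  expect_equal(eoo_km2(shuf), eoo_km2(sq))
  expect_equal(eoo_km2(rbind(sq, sq[2, ])), eoo_km2(sq))
  # interior points do not change the hull
  expect_equal(eoo_km2(rbind(sq, data.frame(lon = 0.5, lat = 0.5))),
               eoo_km2(sq))
})

test_that("EOO agrees with an independent geodesic-area oracle", {
  skip_if_not_installed("geosphere")
  set.seed(3)
  for (i in 1:20) {
    pts <- data.frame(lon = runif(12, 24, 28), lat = runif(12, -22, -18))
    pr <- pts[grDevices::chull(pts$lon, pts$lat), ]
    # spherical geodesic area with the same IUGG radius
    oracle <- geosphere::areaPolygon(as.matrix(pr),
                                     a = EARTH_RADIUS_KM * 1000, f = 0) / 1e6
    # projected straight edges vs geodesic edges diverge slowly with extent
    expect_equal(eoo_km2(pts), oracle, tolerance = 0.01)
  }
})

test_that("AOO counts occupied 2-km squares", {
  one <- data.frame(lon = c(0.001, 0.002), lat = c(0.001, 0.002))
  expect_equal(aoo_km2(one), 4)
  two <- data.frame(lon = c(0, 1), lat = c(0, 0))  # ~111 km apart
  expect_equal(aoo_km2(two), 8)
  # adding a point never decreases AOO
  set.seed(5)
  pts <- data.frame(lon = runif(10, 0, 0.5), lat = runif(10, 0, 0.5))
  for (k in 2:10) {
    expect_gte(aoo_km2(pts[1:k, ]), aoo_km2(pts[1:(k - 1), ]))
  }
})

test_that("location counts use a 10-km occupancy grid", {
  expect_identical(count_locations(data.frame(lon = 10, lat = 10)), 1L)
  clusters <- data.frame(
    lon = c(0, 0.01, 0.5, 0.51, 1.0, 1.01),   # three clusters > 20 km apart
    lat = rep(0, 6))
  expect_identical(count_locations(clusters), 3L)
  set.seed(6)
  pts <- data.frame(lon = runif(30, 0, 2), lat = runif(30, 0, 2))
  expect_lte(count_locations(pts), 30L)
})

test_that("criterion B thresholds map metrics to categories", {
  expect_identical(criterion_b(list(eoo_km2 = 50, aoo_km2 = 8,
                                    n_locations = 1)), "CR")
  expect_identical(criterion_b(list(eoo_km2 = 15000, aoo_km2 = 1500,
                                    n_locations = 8)), "VU")
  expect_identical(criterion_b(list(eoo_km2 = 1e6, aoo_km2 = 1e5,
                                    n_locations = 500)), "LC")
  expect_identical(criterion_b(list(eoo_km2 = 4000, aoo_km2 = 400,
                                    n_locations = 4)), "EN")
  # NT buffer: just above a VU bound
  expect_identical(criterion_b(list(eoo_km2 = 22000, aoo_km2 = 2200,
                                    n_locations = 11)), "NT")
})

test_that("max-risk combination is a bounded semilattice with NE identity", {
  expect_identical(combine_max_risk("VU", "NT"), "VU")
  expect_identical(combine_max_risk("LC", "LC"), "LC")
  expect_identical(combine_max_risk("NE", "EN"), "EN")
  expect_identical(combine_max_risk("NE", "NE"), "NE")
  cats <- c("LC", "NT", "VU", "EN", "CR", "EX", "NE")
  set.seed(8)
  for (i in 1:2000) {
    abc <- sample(cats, 3, replace = TRUE)
    expect_identical(combine_max_risk(abc[1], abc[2]),
                     combine_max_risk(abc[2], abc[1]))
    expect_identical(
      combine_max_risk(combine_max_risk(abc[1], abc[2]), abc[3]),
      combine_max_risk(abc[1], combine_max_risk(abc[2], abc[3])))
    expect_identical(combine_max_risk(abc[1], abc[1]), abc[1])
  }
})

test_that("reclassification fires exactly one identifiable rule", {
  r <- reclassify("VU", -80, 10)
  expect_identical(r$category, "EN")
  expect_match(r$rule_fired, "VU_loss")
  # totality and single-rule firing over a grid of change values
  for (start in c("LC", "NT", "VU", "EN", "CR")) {
    for (pct in seq(-100, 500, by = 2.5)) {
      out <- reclassify(start, pct, future_km2 = if (pct <= -100) 0 else 10)
      expect_true(out$category %in% c("LC", "NT", "VU", "EN", "CR", "EX"))
      expect_true(nzchar(out$rule_fired))
      # EX is reachable only by total loss or a CR losing > 90%
      if (out$category == "EX") {
        expect_true(pct <= -100 || (start == "CR" && pct < -90))
      }
    }
  }
  expect_error(reclassify("NE", -50, 10), "ranked")
})

test_that("genus assessment applies the table and counts threats", {
  recs <- data.frame(
    species = c("s1", "s2", "s3", "s4", "s5"),
    category_start = c("LC", "VU", "EN", "NT", "CR"),
    net_change_pct = c(-95, -80, 200, -60, -100),
    future_km2 = c(5, 5, 30, 5, 0))
  out <- assess_genus(recs, count_ex_as_threatened = TRUE)
  expect_identical(out$assessments$category_end,
                   c("EN", "EN", "NT", "VU", "EX"))
  expect_identical(out$threatened_count, 4L)
  expect_identical(out$ex_count, 1L)
  expect_identical(nrow(out$assessments), nrow(recs))
  strict <- assess_genus(recs, count_ex_as_threatened = FALSE)
  expect_identical(strict$threatened_count, 3L)
  # unresolved NE starts are a named error
  bad <- recs
  bad$category_start[2] <- "NE"
  expect_error(assess_genus(bad), "s2")
})

test_that("NE species resolve through criterion B plus a prior", {
  pts <- data.frame(lon = c(0, 0.01, 0.02), lat = c(0, 0.01, 0.02))
  expect_identical(resolve_start_category("EN", pts), "EN")  # published wins
  prelim <- criterion_b(criterion_b_metrics(pts))
  expect_identical(resolve_start_category("NE", pts), prelim)
  expect_identical(resolve_start_category("NE", pts, prior = "CR"), "CR")
  expect_error(resolve_start_category("NE"), "cannot resolve")
})
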