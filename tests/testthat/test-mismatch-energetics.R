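# Thinned-region segmentation, perimeters and line-tension energetics.

test_that("a membrane at bulk thickness yields an empty region", {
  g <- grid_spec(32, 32, 10, 10)
  tm <- analytic_thickness_map(function(x, y) rep(4.76, length(x)), g)
  reg <- segment_perturbed_region(tm, delta = 0.15)
  expect_equal(reg$perimeter_total, 0)
  expect_false(any(reg$mask))
  expect_equal(region_perimeter(reg, "bulk_only"), 0)
})

test_that("Gaussian-well contour perimeter matches the closed form", {
  # point-like well: contour radius r* = sigma sqrt(2 ln(A / delta))
  A <- 0.4; sigma <- 1.5; delta <- 0.15
  r_star <- sigma * sqrt(2 * log(A / delta))
  g <- grid_spec(128, 128, 12, 12)
  tm <- analytic_thickness_map(function(x, y)
    4.76 - A * exp(-((x - 6)^2 + (y - 6)^2) / (2 * sigma^2)), g)
  reg <- segment_perturbed_region(tm, delta = delta)
  expect_equal(reg$perimeter_total, 2 * pi * r_star,
               tolerance = 0.02 * 2 * pi * r_star)
  expect_equal(reg$perimeter_protein_facing, 0)
})

test_that("contour perimeter converges to the closed form with grid refinement", {
  A <- 0.4; sigma <- 1.5; delta <- 0.15
  oracle <- 2 * pi * sigma * sqrt(2 * log(A / delta))
  errs <- vapply(c(32L, 64L, 128L), function(n) {
    g <- grid_spec(n, n, 12, 12)
    tm <- analytic_thickness_map(function(x, y)
      4.76 - A * exp(-((x - 6)^2 + (y - 6)^2) / (2 * sigma^2)), g)
    abs(segment_perturbed_region(tm, delta = delta)$perimeter_total - oracle)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("sharp rasterized shapes give textbook perimeters", {
  # disk radius 3, cells 0.05 nm
  g <- grid_spec(160, 160, 8, 8)
  tm <- analytic_thickness_map(function(x, y)
    ifelse((x - 4)^2 + (y - 4)^2 <= 9, 4.4, 4.76), g)
  reg <- segment_perturbed_region(tm, delta = 0.15)
  expect_equal(reg$perimeter_total, 2 * pi * 3,
               tolerance = 0.02 * 2 * pi * 3)
  # axis-aligned square of side a
  a <- 3
  tm2 <- analytic_thickness_map(function(x, y)
    ifelse(abs(x - 4) <= a / 2 & abs(y - 4) <= a / 2, 4.4, 4.76), g)
  reg2 <- segment_perturbed_region(tm2, delta = 0.15)
  expect_equal(reg2$perimeter_total, 4 * a, tolerance = 0.02 * 4 * a)
})

test_that("a uniformly thinned membrane around an occupied disk has no bulk-facing boundary", {
  g <- grid_spec(64, 64, 12, 12)
  tm <- analytic_thickness_map(function(x, y) rep(4.76 - 0.2, length(x)), g)
  occupied <- matrix(FALSE, 64, 64)
  xc <- (seq_len(64) - 0.5) * 12 / 64
  occupied[outer((xc - 6)^2, (xc - 6)^2, `+`) <= 1.5^2] <- TRUE
  om <- structure(list(grid = g, fraction = occupied * 1,
                       occupied = occupied, threshold = 0.5),
                  class = "occupancy_map")
  reg <- segment_perturbed_region(tm, om, delta = 0.15)
  expect_equal(reg$perimeter_bulk_facing, 0)
  expect_gt(reg$perimeter_protein_facing, 0)
  expect_equal(sum(reg$mask) + sum(occupied), 64 * 64)
})

test_that("boundary classes always sum to the total perimeter", {
  A <- 0.4; sigma <- 1.5
  g <- grid_spec(96, 96, 12, 12)
  tm <- analytic_thickness_map(function(x, y)
    4.76 - A * exp(-(pmax(0, sqrt((x - 6)^2 + (y - 6)^2) - 1))^2 /
                     (2 * sigma^2)), g)
  occupied <- matrix(FALSE, 96, 96)
  xc <- (seq_len(96) - 0.5) * 12 / 96
  occupied[outer((xc - 6)^2, (xc - 6)^2, `+`) <= 1^2] <- TRUE
  om <- structure(list(grid = g, fraction = occupied * 1,
                       occupied = occupied, threshold = 0.5),
                  class = "occupancy_map")
  reg <- segment_perturbed_region(tm, om, delta = 0.15)
  expect_equal(reg$perimeter_bulk_facing + reg$perimeter_protein_facing,
               reg$perimeter_total, tolerance = 1e-9)
  expect_gt(reg$perimeter_protein_facing, 0)
  expect_gt(reg$perimeter_bulk_facing, 0)
})

test_that("raising the threshold shrinks the mask and the contour", {
  A <- 0.4; sigma <- 1.5
  g <- grid_spec(96, 96, 12, 12)
  tm <- analytic_thickness_map(function(x, y)
    4.76 - A * exp(-((x - 6)^2 + (y - 6)^2) / (2 * sigma^2)), g)
  deltas <- c(0.1, 0.15, 0.2, 0.3)
  regs <- lapply(deltas, function(d) segment_perturbed_region(tm, delta = d))
  areas <- vapply(regs, function(r) sum(r$mask), 0)
  perims <- vapply(regs, function(r) r$perimeter_bulk_facing, 0)
  expect_true(all(diff(areas) <= 0))
  expect_true(all(diff(perims) <= 0))
})

test_that("fully occupied grids are rejected", {
  g <- grid_spec(16, 16, 10, 10)
  tm <- analytic_thickness_map(function(x, y) rep(4.4, length(x)), g)
  occ <- structure(list(grid = g, fraction = matrix(1, 16, 16),
                        occupied = matrix(TRUE, 16, 16), threshold = 0.5),
                   class = "occupancy_map")
  expect_error(segment_perturbed_region(tm, occ, delta = 0.15), "occupied")
})

test_that("perimeter change reproduces the reported complexation arithmetic", {
  expect_equal(perimeter_change(c(13.6, 7.1), 13.3), 7.4)
  expect_equal(perimeter_change(c(13.6, 7.1), 16.7), 4.0)
  expect_equal(perimeter_change(c(5, 5), 10), 0)
  expect_error(perimeter_change(c(-1, 5), 3))
})

test_that("line-tension intervals reproduce the reported free-energy ranges", {
  e1 <- mismatch_free_energy(7.4, 1, 3)
  expect_equal(c(e1$dg_low, e1$dg_high), c(-3.2, -1.1))
  e2 <- mismatch_free_energy(4.0, 1, 3)
  expect_equal(c(e2$dg_low, e2$dg_high), c(-1.7, -0.6))
  e0 <- mismatch_free_energy(0, 1, 3)
  expect_equal(c(e0$dg_low, e0$dg_high), c(0, 0))
})

test_that("mismatch free energy is exactly linear in both arguments", {
  base <- mismatch_free_energy(2, 1.5, 1.5, precision = 12L)$dg_low
  for (f in c(0.5, 2, 7)) {
    expect_equal(mismatch_free_energy(2 * f, 1.5, 1.5, precision = 12L)$dg_low,
                 f * base, tolerance = 1e-9)
    expect_equal(mismatch_free_energy(2, 1.5 * f, 1.5 * f,
                                      precision = 12L)$dg_low,
                 f * base, tolerance = 1e-9)
  }
  # sign convention: positive perimeter reduction means stabilization
  expect_lt(mismatch_free_energy(1, 1, 3)$dg_low, 0)
  expect_gt(mismatch_free_energy(-1, 1, 3)$dg_high, 0)
})

test_that("end-to-end synthetic complexation recovers the analytic perimeter change", {
  # isolated inclusions and a merged complex, all with closed-form contours
  A <- 0.4; sigma <- 1.5; delta <- 0.15
  r_star <- sigma * sqrt(2 * log(A / delta))
  build <- function(R, seed) {
    fp <- footprint_disk(c(7, 7), R)
    spec <- membrane_spec(14, 14, inclusions = list(inclusion(fp, A, sigma)),
                          roughness_sd = 0, areal_density = 2, seed = seed)
    snaps <- gen_membrane_snapshots(spec, 60)
    g <- grid_spec(96, 96, 14, 14)
    surf <- map_leaflet_surfaces(snaps, g)
    tm <- thickness_map(surf$upper, surf$lower)
    om <- occupancy_map(snaps, g, threshold = 0.5)
    segment_perturbed_region(tm, om, delta = delta)
  }
  p_iso1 <- region_perimeter(build(0.8, 31), "bulk_only")
  p_iso2 <- region_perimeter(build(0.5, 32), "bulk_only")
  p_assoc <- region_perimeter(build(1.0, 33), "bulk_only")
  dp <- perimeter_change(c(p_iso1, p_iso2), p_assoc)
  dp_true <- 2 * pi * ((0.8 + r_star) + (0.5 + r_star) - (1.0 + r_star))
  expect_equal(dp, dp_true, tolerance = 0.05 * dp_true)
})
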