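# Leaflet surfaces, thickness maps, occupancy maps, local distributions.

test_that("flat noiseless membrane maps to constant leaflet surfaces", {
  spec <- membrane_spec(10, 10, roughness_sd = 0, areal_density = 1.5,
                        seed = 3)
  snaps <- gen_membrane_snapshots(spec, 50)
  g <- grid_spec(32, 32, 10, 10)
  surf <- map_leaflet_surfaces(snaps, g)
  expect_equal(max(abs(surf$upper$mean - 2.38)), 0, tolerance = 1e-12)
  expect_equal(max(abs(surf$lower$mean + 2.38)), 0, tolerance = 1e-12)
  tm <- thickness_map(surf$upper, surf$lower)
  expect_equal(max(abs(tm$mean_thickness - 4.76)), 0, tolerance = 1e-12)
})

test_that("sampled thickness follows the analytic well field", {
  fp <- footprint_disk(c(6, 6), 0.5)
  spec <- membrane_spec(12, 12, inclusions = list(inclusion(fp, 0.4, 1.5)),
                        roughness_sd = 0.1, areal_density = 1.5, seed = 9)
  snaps <- gen_membrane_snapshots(spec, 500)
  g <- grid_spec(64, 64, 12, 12)
  surf <- map_leaflet_surfaces(snaps, g)
  tm <- thickness_map(surf$upper, surf$lower)
  xc <- (seq_len(64) - 0.5) * 12 / 64
  h_true <- outer(xc, xc, function(x, y) analytic_thickness(spec, x, y))
  obs <- !tm$interpolated
  # superposition property: deviation within 3 x SEM at >= 95% of cells
  sem <- sqrt(2) * spec$roughness_sd / sqrt(pmax(tm$n_obs, 1))
  frac <- mean((abs(tm$mean_thickness - h_true) <= 3 * sem)[obs])
  expect_gte(frac, 0.95)
  # well locus: thickness near the footprint edge close to h0 - A
  d_edge <- abs(sqrt(outer((xc - 6)^2, (xc - 6)^2, `+`)) - 0.5)
  locus <- d_edge < 0.15 & obs
  expect_equal(mean(tm$mean_thickness[locus]), 4.36, tolerance = 0.02)
})

test_that("single observed lipid leaves all other cells interpolated", {
  fr <- list(upper_P = cbind(x = 0.1, y = 0.1, z = 2.38),
             lower_P = cbind(x = 0.1, y = 0.1, z = -2.38),
             protein_atoms = matrix(numeric(0), ncol = 3))
  snaps <- make_snapshot_set(list(fr), box = c(8, 8, 10))
  g <- grid_spec(16, 16, 8, 8)
  surf <- map_leaflet_surfaces(snaps, g)
  expect_equal(sum(!surf$upper$interpolated), 1L)
  expect_equal(sum(surf$upper$n_obs), 1L)
  # interpolation from a single value reproduces that value everywhere
  expect_equal(max(abs(surf$upper$mean - 2.38)), 0, tolerance = 1e-12)
})

test_that("thickness map rejects mismatched grids and inverted leaflets", {
  spec <- membrane_spec(10, 10, roughness_sd = 0, areal_density = 1.5,
                        seed = 4)
  snaps <- gen_membrane_snapshots(spec, 2)
  s1 <- map_leaflet_surfaces(snaps, grid_spec(16, 16, 10, 10))
  s2 <- map_leaflet_surfaces(snaps, grid_spec(32, 32, 10, 10))
  expect_error(thickness_map(s1$upper, s2$lower), "grid mismatch")
  expect_error(thickness_map(s1$lower, s1$upper), "inversion")
  empty <- make_snapshot_set(list(list(
    upper_P = cbind(x = 1, y = 1, z = 2),
    lower_P = matrix(numeric(0), ncol = 3),
    protein_atoms = matrix(numeric(0), ncol = 3))), box = c(10, 10, 10))
  expect_error(map_leaflet_surfaces(empty, grid_spec(16, 16, 10, 10)),
               "lower")
})

test_that("occupancy maps recover footprint areas", {
  # cell area counts bias the raster area by ~ perimeter * cell/2, so the
  # closed-form comparison needs a fine grid and a dense protein slab
  g <- grid_spec(192, 192, 12, 12)
  fp <- footprint_disk(c(6, 6), 1.5)
  spec <- membrane_spec(12, 12, inclusions = list(inclusion(fp, 0.3, 1)),
                        roughness_sd = 0, areal_density = 1.5, seed = 11)
  snaps <- gen_membrane_snapshots(spec, 2, protein_density = 500)
  om <- occupancy_map(snaps, g)
  occ_area <- sum(om$occupied) * g$dx * g$dy
  expect_equal(occ_area, pi * 1.5^2, tolerance = 0.05)

  g2 <- grid_spec(300, 300, 12, 12)
  hs <- footprint_horseshoe(c(6, 6), 2.2, 1.1, opening_angle = pi / 3)
  spec2 <- membrane_spec(12, 12, inclusions = list(inclusion(hs, 0.3, 1)),
                         roughness_sd = 0, areal_density = 1.5, seed = 12)
  snaps2 <- gen_membrane_snapshots(spec2, 2, protein_density = 1500)
  om2 <- occupancy_map(snaps2, g2)
  expect_equal(sum(om2$occupied) * g2$dx * g2$dy, footprint_area(hs),
               tolerance = 0.05 * footprint_area(hs))
})

test_that("occupancy of a protein-free system is zero with a warning", {
  spec <- membrane_spec(10, 10, roughness_sd = 0, areal_density = 1.5,
                        seed = 13)
  snaps <- gen_membrane_snapshots(spec, 2)
  expect_warning(om <- occupancy_map(snaps, grid_spec(16, 16, 10, 10)),
                 "no protein")
  expect_true(all(om$fraction == 0))
})

test_that("maps are invariant under translation by a box length", {
  fp <- footprint_disk(c(5, 5), 0.8)
  spec <- membrane_spec(10, 10, inclusions = list(inclusion(fp, 0.3, 1.2)),
                        roughness_sd = 0.1, areal_density = 1.5, seed = 21)
  snaps <- gen_membrane_snapshots(spec, 10)
  shifted <- snaps
  shifted$frames <- lapply(snaps$frames, function(fr) {
    for (f in c("upper_P", "lower_P", "protein_atoms"))
      if (nrow(fr[[f]]) > 0) fr[[f]][, 1] <- fr[[f]][, 1] + 10
    fr
  })
  g <- grid_spec(32, 32, 10, 10)
  a <- map_leaflet_surfaces(snaps, g)
  b <- map_leaflet_surfaces(shifted, g)
  expect_identical(a$upper$mean, b$upper$mean)
  expect_identical(a$lower$n_obs, b$lower$n_obs)
  expect_identical(occupancy_map(snaps, g)$fraction,
                   occupancy_map(shifted, g)$fraction)
})

test_that("grid refinement changes the spatial-mean thickness by < 0.5%", {
  fp <- footprint_disk(c(6, 6), 0.5)
  spec <- membrane_spec(12, 12, inclusions = list(inclusion(fp, 0.4, 1.5)),
                        roughness_sd = 0.05, areal_density = 2, seed = 15)
  snaps <- gen_membrane_snapshots(spec, 100)
  m <- vapply(c(24L, 48L), function(n) {
    g <- grid_spec(n, n, 12, 12)
    surf <- map_leaflet_surfaces(snaps, g)
    mean(thickness_map(surf$upper, surf$lower)$mean_thickness)
  }, 0)
  expect_lt(abs(m[2] - m[1]) / m[1], 0.005)
})

test_that("map spatial mean agrees with the per-lipid thickness estimator", {
  fp <- footprint_disk(c(6, 6), 0.5)
  spec <- membrane_spec(12, 12, inclusions = list(inclusion(fp, 0.4, 1.5)),
                        roughness_sd = 0.1, areal_density = 2, seed = 16)
  snaps <- gen_membrane_snapshots(spec, 200)
  g <- grid_spec(32, 32, 12, 12)
  surf <- map_leaflet_surfaces(snaps, g)
  tm <- thickness_map(surf$upper, surf$lower)
  obs <- !tm$interpolated
  lipidwise <- mean(vapply(snaps$frames, function(fr)
    mean(fr$upper_P[, 3]) - mean(fr$lower_P[, 3]), 0))
  expect_equal(mean(tm$mean_thickness[obs]), lipidwise, tolerance = 0.01)
})

test_that("local thickness distribution is a point mass for a flat membrane", {
  spec <- membrane_spec(10, 10, roughness_sd = 0, areal_density = 3, seed = 6)
  snaps <- gen_membrane_snapshots(spec, 30)
  g <- grid_spec(16, 16, 10, 10)
  d <- suppressWarnings(
    local_thickness_distribution(snaps, g, c(5, 5), cutoff = 2))
  expect_equal(max(abs(d$values - 4.76)), 0, tolerance = 1e-12)
  expect_equal(d$mean, 4.76, tolerance = 1e-12)
})

test_that("local distribution near a well is depleted by the analytic amount", {
  fp <- footprint_disk(c(6, 6), 0.5)
  spec <- membrane_spec(12, 12, inclusions = list(inclusion(fp, 0.4, 1.5)),
                        roughness_sd = 0.05, areal_density = 3, seed = 17)
  snaps <- gen_membrane_snapshots(spec, 150)
  g <- grid_spec(48, 48, 12, 12)
  ref <- c(6.5, 6)  # footprint edge
  cutoff <- 1.6
  d <- local_thickness_distribution(snaps, g, ref, cutoff = cutoff)
  # oracle: analytic mean of h over unoccupied selected cell centers
  xc <- (seq_len(48) - 0.5) * 12 / 48
  grd <- expand.grid(x = xc, y = xc)
  sel <- sqrt((grd$x - ref[1])^2 + (grd$y - ref[2])^2) <= cutoff &
    !footprint_contains(fp, grd$x, grd$y)
  h_bar <- mean(analytic_thickness(spec, grd$x[sel], grd$y[sel]))
  expect_lt(h_bar, 4.76)  # depletion present
  expect_equal(d$mean, h_bar, tolerance = 0.02)
})

test_that("degenerate local selections error out", {
  spec <- membrane_spec(10, 10, roughness_sd = 0, areal_density = 3, seed = 6)
  snaps <- gen_membrane_snapshots(spec, 2)
  g <- grid_spec(16, 16, 10, 10)
  expect_error(
    suppressWarnings(
      local_thickness_distribution(snaps, g, c(5, 5), cutoff = 0.3)),
    "diagonal")
})
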