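# zone occupancy, LPI, kernel density, hotspots

test_that("zone occupancy counts fixes inside each zone", {
  shade <- zone("shade", buffer_geometry(c(50, 50), 10), buffered = TRUE)
  inside <- make_traj(runif(200, 45, 55), runif(200, 45, 55))
  oc <- zone_occupancy(inside, shade)
  expect_equal(oc$pct_of_day, 100)
  expect_equal(oc$hours, 24)
  expect_error(zone_occupancy(make_traj(numeric(0), numeric(0)), shade))
})

test_that("occupancy fractions match a per-point oracle and disjoint strips partition", {
  set.seed(61)
  pad <- default_paddock()
  x <- runif(2000, 0.01, 129.99)
  y <- runif(2000, 0.01, 99.99)
  tr <- make_traj(x, y)
  oc <- zone_occupancy(tr, pad$zones)
  for (i in seq_len(nrow(oc))) {
    ring <- pad$zones[[oc$zone[i]]]$geometry$exterior
    expect_equal(oc$n_inside[i], sum(pip_oracle(x, y, ring)))
  }
  strips <- oc[oc$zone %in% c("weed_strip", "bermudagrass_strip"), ]
  expect_equal(sum(strips$pct_of_day), 100)
})

test_that("LPI is the time/area ratio with its fixed points", {
  expect_equal(round(lpi(0.373, 0.52)$lpi, 1), 0.7)
  expect_equal(round(lpi(0.291, 0.48)$lpi, 1), 0.6)
  expect_equal(lpi(0.3, 0.3)$lpi, 1.0)
  expect_error(lpi(0.5, 0), "area_fraction")
  expect_error(lpi(1.5, 0.5), "time_fraction")
})

test_that("area-weighted LPIs of exhaustive disjoint zones average to one", {
  set.seed(62)
  pad <- default_paddock()
  tr <- make_traj(runif(5000, 0.01, 129.99), runif(5000, 0.01, 99.99))
  zs <- pad$zones[c("weed_strip", "bermudagrass_strip")]
  oc <- zone_occupancy(tr, zs)
  total <- polygon_area(pad$boundary)
  acc <- 0
  for (i in 1:2) {
    af <- zs[[oc$zone[i]]]$area_m2 / total
    acc <- acc + af * lpi(oc$pct_of_day[i] / 100, af)$lpi
  }
  expect_equal(acc, 1, tolerance = 1e-9)
})

test_that("every zone's LPI approaches one under uniform use", {
  set.seed(63)
  n <- 1e5
  pad <- default_paddock()
  tr <- make_traj(runif(n, 0, 130), runif(n, 0, 100))
  oc <- zone_occupancy(tr, pad$zones)
  total <- polygon_area(pad$boundary)
  for (i in seq_len(nrow(oc))) {
    af <- pad$zones[[oc$zone[i]]]$area_m2 / total
    expect_lt(abs(lpi(oc$pct_of_day[i] / 100, af)$lpi - 1), 0.05)
  }
})

test_that("kernel density conserves mass and peaks at a lone point", {
  # the half-cell margin puts the lone point exactly on a cell center
  g <- kernel_density(50, 50, bandwidth_m = 10, cell_size_m = 1,
                      margin_m = 10.5)
  expect_equal(grid_mass(g), 1, tolerance = 0.01)
  peak <- which(g$values == max(g$values), arr.ind = TRUE)
  # the maximum cell contains the point
  expect_equal(unname(g$x0 + (peak[1, "col"] - 0.5) * g$cell_size_m), 50)
  expect_equal(unname(g$y0 + (peak[1, "row"] - 0.5) * g$cell_size_m), 50)
  # radial symmetry about the point
  expect_equal(g$values[peak[1, "row"] - 3, peak[1, "col"]],
               g$values[peak[1, "row"] + 3, peak[1, "col"]])
  expect_equal(g$values[peak[1, "row"], peak[1, "col"] - 5],
               g$values[peak[1, "row"], peak[1, "col"] + 5])
  set.seed(64)
  x <- runif(3000, 0, 100); y <- runif(3000, 0, 60)
  for (k in c("quartic", "gaussian", "epanechnikov")) {
    gk <- kernel_density(x, y, bandwidth_m = 8, cell_size_m = 1, kernel = k)
    expect_lt(abs(grid_mass(gk) - 3000) / 3000, 0.01)
  }
  expect_warning(kernel_density(x, y, bandwidth_m = 2, cell_size_m = 5),
                 "undersampled")
})

test_that("mirrored clusters produce mirrored densities", {
  # half-cell margin makes the grid symmetric about the midpoint of the
  # two cluster locations
  x <- c(rep(20, 50), rep(80, 50))
  y <- rep(30, 100)
  g <- kernel_density(x, y, bandwidth_m = 10, cell_size_m = 1,
                      margin_m = 10.5)
  expect_equal(g$values, g$values[, rev(seq_len(g$n_cols))], tolerance = 1e-12)
})

test_that("hotspots flag only strictly-above-quantile cells", {
  flat <- structure(list(x0 = 0, y0 = 0, cell_size_m = 1, n_rows = 6, n_cols = 6,
                         n_points = 36, kernel = "quartic", bandwidth_m = 1,
                         values = matrix(1, 6, 6)), class = "density_grid")
  expect_equal(nrow(hotspot_summary(flat, 0.99)), 0L)
  spiked <- flat
  spiked$values[3, 4] <- 50
  for (q in c(0.5, 0.9, 0.99)) {
    hs <- hotspot_summary(spiked, q)
    expect_true(all(c(3, 4) %in% c(hs$row, hs$col)))
    expect_equal(hs$value[1], 50)
  }
})

test_that("shade attraction produces shade hotspots and LPI above one", {
  cfg <- sim_config(attraction = c(shade = 0.5), gps_noise_sd_m = 0)
  sim <- simulate_trajectory(cfg, seed = 5)
  g <- kernel_density(sim$trajectory, bandwidth_m = 10, cell_size_m = 2)
  hs <- hotspot_summary(g, 0.99)
  shade <- cfg$paddock$zones$shade
  expect_true(any(point_in_polygon(hs$x, hs$y, shade$geometry)))
  oc <- zone_occupancy(sim$trajectory, shade)
  af <- shade$area_m2 / polygon_area(cfg$paddock$boundary)
  expect_gt(lpi(oc$pct_of_day / 100, af)$lpi, 1)
})

test_that("ASCII grid export writes a well-formed raster", {
  g <- kernel_density(c(5, 6), c(5, 7), bandwidth_m = 3, cell_size_m = 1)
  tmp <- tempfile(fileext = ".asc")
  write_asc(g, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "^ncols")
  expect_equal(length(lines), 6 + g$n_rows)
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  expect_equal(sum(body) * g$cell_size_m^2, grid_mass(g), tolerance = 1e-6)
})
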