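# ingestion, cleaning, geofencing, daily segmentation

test_that("CSV logs parse with sorting, dedupe, and bad-row counts", {
  tmp <- tempfile(fileext = ".csv")
  write_collar_csv(tmp, c("2022-07-12T00:00:00", "2022-07-12T00:00:01",
                          "2022-07-12T00:00:02"),
                   lat = rep(30.8633, 3), lon = rep(-85.1847, 3))
  tr <- read_gps_log(tmp, animal_id = "A1")
  rep <- attr(tr, "filter_report")
  expect_equal(n_fixes(tr), 3L)
  expect_equal(rep$n_duplicate, 0L)

  # out-of-order rows get sorted
  write_collar_csv(tmp, c("2022-07-12T00:00:02", "2022-07-12T00:00:00",
                          "2022-07-12T00:00:01"),
                   lat = c(30.3, 30.1, 30.2), lon = rep(-85, 3))
  tr <- read_gps_log(tmp)
  expect_equal(tr$fixes$lat, c(30.1, 30.2, 30.3))
  expect_equal(attr(tr, "filter_report")$n_reordered, 2L)

  # duplicate timestamps keep the first occurrence
  write_collar_csv(tmp, c("2022-07-12T00:00:05", "2022-07-12T00:00:05"),
                   lat = c(30.1, 30.9), lon = rep(-85, 2))
  tr <- read_gps_log(tmp)
  expect_equal(n_fixes(tr), 1L)
  expect_equal(tr$fixes$lat, 30.1)
  expect_equal(attr(tr, "filter_report")$n_duplicate, 1L)

  # unparseable rows are skipped and counted; counts stay balanced
  writeLines(c("time,lat,lon", "2022-07-12T00:00:00,30.1,-85",
               "not-a-time,30.2,-85", "2022-07-12T00:00:01,oops,-85",
               "2022-07-12T00:00:02,30.3,-85"), tmp)
  tr <- read_gps_log(tmp)
  rep <- attr(tr, "filter_report")
  expect_equal(n_fixes(tr), 2L)
  expect_equal(rep$n_bad_rows, 2L)
  expect_equal(rep$n_input, rep$n_kept + rep$n_out_of_boundary + rep$n_duplicate)

  writeLines("time,lat,lon", tmp)
  expect_error(read_gps_log(tmp), "empty")
  expect_error(read_gps_log(tempfile()), "not found")
})

test_that("GPX track points parse into a geographic trajectory", {
  tmp <- tempfile(fileext = ".gpx")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<gpx version="1.1" xmlns="http://www.topografix.com/GPX/1/1"><trk><trkseg>',
    '<trkpt lat="30.8633" lon="-85.1847"><time>2022-07-12T10:00:00Z</time></trkpt>',
    '<trkpt lat="30.8634" lon="-85.1846"><time>2022-07-12T10:00:01Z</time></trkpt>',
    '</trkseg></trk></gpx>'), tmp)
  tr <- read_gps_log(tmp, dialect = "gpx")
  expect_equal(n_fixes(tr), 2L)
  expect_equal(tr$crs, "geographic")
  expect_equal(tr$fixes$lat, c(30.8633, 30.8634))
  p <- project_trajectory(tr)
  expect_equal(p$crs, "planar")
  expect_true(all(is.finite(p$fixes$x)))
})

test_that("geofencing keeps inside/edge fixes, drops outside, and is idempotent", {
  sq <- rect_polygon(0, 0, 1, 1)
  tr <- make_traj(c(0.5, 2, 1), c(0.5, 2, 0.5))   # inside, outside, on edge
  res <- filter_to_boundary(tr, sq)
  expect_equal(n_fixes(res$trajectory), 2L)
  expect_equal(res$report$n_out_of_boundary, 1L)
  expect_equal(res$report$n_input,
               res$report$n_kept + res$report$n_out_of_boundary)
  # all-inside identity
  tr2 <- make_traj(runif(10, 0.1, 0.9), runif(10, 0.1, 0.9))
  res2 <- filter_to_boundary(tr2, sq)
  expect_equal(res2$trajectory$fixes, tr2$fixes)
  # idempotence
  res3 <- filter_to_boundary(res$trajectory, sq)
  expect_equal(res3$trajectory$fixes, res$trajectory$fixes)
  expect_equal(res3$report$n_out_of_boundary, 0L)
})

test_that("geofencing agrees with the point-in-polygon oracle on a concave fence", {
  set.seed(31)
  cp <- c_polygon()
  x <- runif(1000, -0.5, 4.5)
  y <- runif(1000, -0.5, 4.5)
  res <- filter_to_boundary(make_traj(x, y), cp)
  keep_oracle <- pip_oracle(x, y, cp$exterior)
  expect_equal(n_fixes(res$trajectory), sum(keep_oracle))
  expect_equal(res$trajectory$fixes$x, x[keep_oracle])
})

test_that("day splitting partitions at local midnight with coverage flags", {
  # 48 h of continuous 1 Hz fixes -> two complete days, no fix shared
  n <- 2 * 86400
  tr <- make_traj(rep(1, n), rep(1, n))
  days <- split_days(tr, tz = "UTC")
  expect_length(days, 2L)
  expect_false(any(vapply(days, function(s) attr(s, "excluded"), TRUE)))
  expect_equal(sum(vapply(days, n_fixes, 1L)), n_fixes(tr))
  expect_equal(format(days[[1]]$fixes$time[86400], "%H:%M:%S"), "23:59:59")
  expect_equal(format(days[[2]]$fixes$time[1], "%H:%M:%S"), "00:00:00")

  # 50% dropout day flagged below min_coverage = 0.8
  half <- make_traj(rep(1, 43200), rep(1, 43200))
  seg <- split_days(half, min_coverage = 0.8, fix_rate_hz = 1)
  expect_true(attr(seg[[1]], "excluded"))
  expect_equal(attr(seg[[1]], "coverage"), 0.5)
  seg2 <- split_days(half, min_coverage = 0.4, fix_rate_hz = 1)
  expect_false(attr(seg2[[1]], "excluded"))
})

test_that("timezone shifts the day boundary", {
  # fixes around 03:00 UTC split differently under UTC-4
  tt <- T0 + c(-3 * 3600, 3 * 3600)
  tr <- gps_trajectory(data.frame(time = tt, x = c(0, 1), y = c(0, 1)),
                       crs = "planar")
  expect_length(split_days(tr, tz = "UTC"), 2L)
  expect_length(split_days(tr, tz = "Etc/GMT+4"), 1L)
})

test_that("trajectory CSV round-trips through the reader", {
  tr <- make_traj(c(1.5, 2.5, 3.5), c(4, 5, 6), animal_id = "A2",
                  paddock_id = "P07")
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tmp)
  back <- read_gps_log(tmp, columns = list(time = "iso_time", x = "x", y = "y"),
                       coords = "planar", animal_id = "A2", paddock_id = "P07")
  expect_equal(back$fixes$x, tr$fixes$x)
  expect_equal(back$fixes$y, tr$fixes$y)
  expect_equal(as.numeric(back$fixes$time), as.numeric(tr$fixes$time))
})
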