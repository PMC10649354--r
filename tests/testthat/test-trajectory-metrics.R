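# step distances, daily distance, rate of travel, resampling

test_that("stationary runs collapse to the first fix and preserve elapsed time", {
  tr <- make_traj(c(rep(0, 10), 5), c(rep(0, 10), 0))  # (0,0)@t0..t9, (5,0)@t10
  col <- collapse_stationary(tr)
  expect_equal(n_fixes(col), 2L)
  st <- step_metrics(col)
  expect_equal(st$dt_s, 10)
  expect_equal(st$distance_m, 5)
  # no repeats -> identity
  tr2 <- make_traj(1:5, 1:5)
  expect_equal(collapse_stationary(tr2)$fixes[, c("x", "y")],
               tr2$fixes[, c("x", "y")])
  # all identical -> single fix, zero steps
  tr3 <- make_traj(rep(2, 50), rep(3, 50))
  col3 <- collapse_stationary(tr3)
  expect_equal(n_fixes(col3), 1L)
  expect_equal(nrow(step_metrics(col3)), 0L)
})

test_that("step metrics follow the Pythagorean distance and m/min speed", {
  tr <- make_traj(c(0, 3), c(0, 4), dt = 60)
  st <- step_metrics(tr)
  expect_equal(st$distance_m, 5)
  expect_equal(st$speed_m_per_min, 5)
  tr2 <- make_traj(c(0, 3), c(0, 4), dt = 120)
  expect_equal(step_metrics(tr2)$speed_m_per_min, 2.5)
  # random walk total equals an independent per-step summation
  set.seed(41)
  x <- cumsum(rnorm(101)); y <- cumsum(rnorm(101))
  st3 <- step_metrics(make_traj(x, y))
  brute <- 0
  for (i in 1:100) brute <- brute + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  expect_equal(daily_distance(st3), brute)
})

test_that("daily distance is additive over partitions and gap steps drop out", {
  set.seed(42)
  x <- cumsum(rnorm(500)); y <- cumsum(rnorm(500))
  st <- step_metrics(make_traj(x, y))
  d <- daily_distance(st)
  split_at <- 200
  expect_equal(sum(st$distance_m[1:split_at]) +
                 sum(st$distance_m[(split_at + 1):nrow(st)]), d)
  # a recording gap contributes no distance
  tt <- T0 + c(0, 1, 2, 1000, 1001)
  tr <- gps_trajectory(data.frame(time = tt, x = c(0, 1, 2, 50, 51), y = 0),
                       crs = "planar")
  stg <- step_metrics(tr, max_gap_s = 300)
  expect_equal(sum(!stg$valid), 1L)
  expect_equal(daily_distance(stg), 1 + 1 + 1)
  # zero movement
  expect_equal(daily_distance(step_metrics(make_traj(c(0, 0), c(0, 0) + c(0, 0)))), 0)
})

test_that("collapsed resting runs are not mistaken for recording gaps", {
  # 30 min stationary, then a move: continuous 1 Hz recording throughout
  n <- 1800
  tr <- make_traj(c(rep(0, n), 3), c(rep(0, n), 4))
  st <- step_metrics(collapse_stationary(tr), max_gap_s = 300)
  expect_true(all(st$valid))
  expect_equal(daily_distance(st), 5)
  # the same span with fixes genuinely missing is a gap
  tt <- T0 + c(0, 1800)
  tr2 <- gps_trajectory(data.frame(time = tt, x = c(0, 3), y = c(0, 4)),
                        crs = "planar")
  expect_false(any(step_metrics(tr2, max_gap_s = 300)$valid))
})

test_that("daily distance is invariant under rigid transforms", {
  set.seed(43)
  x <- cumsum(rnorm(300)); y <- cumsum(rnorm(300))
  d0 <- daily_distance(step_metrics(make_traj(x, y)))
  th <- 1.1
  xr <- cos(th) * x - sin(th) * y + 500
  yr <- sin(th) * x + cos(th) * y - 200
  expect_equal(daily_distance(step_metrics(make_traj(xr, yr))), d0,
               tolerance = 1e-12)
})

test_that("resampling keeps identity at native rate and shortens sinuous paths", {
  set.seed(44)
  n <- 7200
  x <- cumsum(rnorm(n, sd = 0.2)); y <- cumsum(rnorm(n, sd = 0.2))
  tr <- make_traj(x, y)
  expect_equal(resample_trajectory(tr, 1)$fixes, tr$fixes)
  d1 <- daily_distance(step_metrics(tr, max_gap_s = Inf))
  d600 <- daily_distance(step_metrics(resample_trajectory(tr, 600),
                                      max_gap_s = Inf))
  expect_lt(d600, d1)
  # monotone non-increasing across coarser intervals (triangle inequality)
  dists <- vapply(c(1, 10, 60, 600), function(iv)
    daily_distance(step_metrics(resample_trajectory(tr, iv), max_gap_s = Inf)), 0)
  expect_true(all(diff(dists) <= 1e-9))
  expect_error(resample_trajectory(tr, 0.5), "native")
})

test_that("straight constant-velocity paths keep their length at any interval", {
  tr <- make_traj(seq(0, 999, by = 1), seq(0, 1998, by = 2))
  d1 <- daily_distance(step_metrics(tr, max_gap_s = Inf))
  for (iv in c(10, 100, 250))
    expect_equal(daily_distance(step_metrics(resample_trajectory(tr, iv),
                                             max_gap_s = Inf)), d1,
                 tolerance = 1e-9)
})

test_that("mean travel rate over collapsed steps bounds distance over wall time", {
  set.seed(45)
  moves <- cumsum(sample(c(0, 0, 0, 1), 2000, replace = TRUE))
  tr <- make_traj(moves, rep(0, 2000))
  col <- collapse_stationary(tr)
  st <- step_metrics(col, max_gap_s = Inf)
  wall_rate <- daily_distance(st) / (as.numeric(diff(range(tr$fixes$time)),
                                                units = "mins"))
  expect_gte(mean_travel_rate(st) + 1e-12, wall_rate)
})

test_that("daily metrics summarise a segment and flag excluded days", {
  tr <- make_traj(c(rep(0, 100), seq(1, 50)), c(rep(0, 100), rep(0, 50)),
                  animal_id = "A1", paddock_id = "P01")
  attr(tr, "excluded") <- TRUE
  attr(tr, "coverage") <- 0.3
  dm <- daily_metrics(tr)
  expect_true(dm$excluded)
  expect_equal(dm$distance_m_per_day, 50)
  expect_equal(dm$n_fixes, 150)
})
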