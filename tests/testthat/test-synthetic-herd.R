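# synthetic herd generator: reproducibility, recovery, calibration, bias

test_that("simulation is reproducible and respects the fence", {
  cfg <- sim_config(gps_noise_sd_m = 0)
  s1 <- simulate_trajectory(cfg, seed = 7)
  s2 <- simulate_trajectory(cfg, seed = 7)
  expect_identical(s1$trajectory$fixes, s2$trajectory$fixes)
  expect_identical(s1$truth$daily, s2$truth$daily)
  s3 <- simulate_trajectory(cfg, seed = 8)
  expect_false(identical(s1$trajectory$fixes$x, s3$trajectory$fixes$x))
  # zero noise: every fix inside the paddock polygon (closed boundary)
  expect_true(all(point_in_polygon(s1$trajectory$fixes$x,
                                   s1$trajectory$fixes$y,
                                   cfg$paddock$boundary)))
  expect_equal(n_fixes(s1$trajectory), 86400)
})

test_that("inconsistent separable configurations are rejected", {
  st <- data.frame(state = c("resting", "grazing", "traveling"),
                   mean_bout_s = c(1800, 900, 180),
                   speed_mu_m_per_min = c(0, 8, 20),  # travel below band
                   speed_sdlog = c(0, 0.3, 0.2), crw_rho = c(0, 0.6, 0.9))
  expect_error(sim_config(states = st), "traveling")
  st$speed_mu_m_per_min <- c(0, 1, 40)                # graze below band
  expect_error(sim_config(states = st), "grazing")
  expect_error(sim_config(target_budget = c(resting = 50, grazing = 30,
                                            traveling = 30)), "sum to 100")
})

test_that("designed budgets and distances are recovered without noise", {
  cfg <- sim_config(target_budget = c(resting = 85, grazing = 9, traveling = 6),
                    gps_noise_sd_m = 0)
  sim <- simulate_trajectory(cfg, seed = 42)
  st <- step_metrics(collapse_stationary(sim$trajectory))
  expect_equal(daily_distance(st), sim$truth$daily$distance_m,
               tolerance = 1e-6)
  b <- daily_budget(st)
  expect_lt(abs(b$resting_pct - 85), 1)
  expect_lt(abs(b$grazing_pct - 9), 1)
  expect_lt(abs(b$traveling_pct - 6), 1)
  # truth labels partition all fixes
  expect_equal(sum(table(sim$truth$fixes$state)), 86400)
})

test_that("5 m location error biases budgets toward grazing by a bounded amount", {
  cfg <- sim_config(target_budget = c(resting = 85, grazing = 9, traveling = 6),
                    gps_noise_sd_m = 5)
  sim <- simulate_trajectory(cfg, seed = 42)
  b <- daily_budget(step_metrics(collapse_stationary(sim$trajectory)))
  expect_lt(abs(b$resting_pct - 85), 5)
  expect_lt(abs(b$grazing_pct - 9), 5)
  expect_lt(abs(b$traveling_pct - 6), 5)
  expect_gt(b$grazing_pct, 9)   # leakage direction: resting -> grazing
})

test_that("study simulation emits a readable file tree that round-trips", {
  out <- file.path(tempdir(), "study_rt")
  unlink(out, recursive = TRUE)
  cfg <- study_config(n_periods = 1, days_per_period = 1,
                      base = sim_config(fix_rate_hz = 1 / 60))
  man <- simulate_study(cfg, out, seed = 3)
  expect_length(man$collars, 24L)          # 12 paddocks x 2 testers
  expect_true(file.exists(file.path(out, "design.csv")))
  expect_true(file.exists(file.path(out, "zones.geojson")))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  # RCBD layout
  des <- utils::read.csv(file.path(out, "design.csv"))
  expect_true(all(table(unique(des[, c("paddock_id", "block", "treatment")])$block,
                        unique(des[, c("paddock_id", "block", "treatment")])$treatment) == 1))
  # I/O inverse: reading an emitted collar file reproduces the trajectory
  tr <- read_gps_log(man$collars[1], columns = list(time = "iso_time",
                                                    x = "x", y = "y"),
                     coords = "planar")
  raw <- utils::read.csv(man$collars[1])
  expect_equal(n_fixes(tr), nrow(raw))
  expect_equal(tr$fixes$x, raw$x)
  # determinism: the same seed rewrites byte-identical collar files
  out2 <- file.path(tempdir(), "study_rt2")
  unlink(out2, recursive = TRUE)
  simulate_study(cfg, out2, seed = 3)
  expect_identical(readLines(man$collars[1]),
                   readLines(file.path(out2, "collars", basename(man$collars[1]))))
})

test_that("metrics-level study draws mirror the designed treatment contrast", {
  cfg <- study_config(n_periods = 5, days_per_period = 3)
  md <- simulate_study_metrics(cfg, seed = 19)
  expect_equal(nrow(md), 12 * 2 * 15)
  agg <- tapply(md$distance_m_per_day, md$treatment, mean)
  expect_gt(agg[["weed_infested"]], agg[["weed_free"]])
  # analytic expectation: budget shares x state speeds
  sp <- cfg$base$states$speed_mu_m_per_min
  expected_wi <- 8.9 / 100 * 1440 * sp[2] + 6.0 / 100 * 1440 * sp[3]
  expect_lt(abs(agg[["weed_infested"]] - expected_wi) / expected_wi, 0.05)
})

test_that("distance bias grows with GPS noise and falls with coarser sampling", {
  b <- bias_experiment(n_rep = 5, seed = 13)
  noise <- tapply(b$bias_m[b$kind == "gps_noise"],
                  b$param[b$kind == "gps_noise"], mean)
  noise <- noise[order(as.numeric(names(noise)))]
  expect_equal(unname(noise[1]), 0)            # sigma = 0 at native rate
  expect_true(all(diff(noise) > 0))            # monotone measurement error
  intr <- tapply(b$bias_m[b$kind == "sampling_interval"],
                 b$param[b$kind == "sampling_interval"], mean)
  intr <- intr[order(as.numeric(names(intr)))]
  expect_equal(unname(intr[1]), 0)             # native interval
  expect_true(all(diff(intr) < 0))             # monotone interpolation error
  expect_true(all(intr[-1] < 0))
})
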