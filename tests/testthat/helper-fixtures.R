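# shared fixtures and independent oracles, built in code

T0 <- as.POSIXct("2022-07-12 00:00:00", tz = "UTC")

# trajectory from coordinate vectors at a fixed rate
make_traj <- function(x, y, dt = 1, t0 = T0, ...) {
  gps_trajectory(data.frame(time = t0 + (seq_along(x) - 1) * dt, x = x, y = y),
                 crs = "planar", ...)
}

# independent point-in-polygon oracle: winding number by angle summation,
# a different algorithm from the crossing-number implementation under test
pip_oracle <- function(px, py, ring) {
  total <- rep(0, length(px))
  n <- nrow(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- ring[i, 1] - px; ay <- ring[i, 2] - py
    bx <- ring[j, 1] - px; by <- ring[j, 2] - py
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  abs(total) > pi
}

# random simple (star-shaped) polygon: sorted angles around a center
random_polygon <- function(n_vertices, cx = 0, cy = 0, rmin = 1, rmax = 10) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, rmin, rmax)
  planar_polygon(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# a C-shaped (concave) polygon with a notch on the right
c_polygon <- function() {
  planar_polygon(cbind(c(0, 4, 4, 1, 1, 4, 4, 0), c(0, 0, 1, 1, 3, 3, 4, 4)))
}

# hand-built step series (class constructor for budget tests)
make_steps <- function(dt_s, speed_m_per_min, valid = TRUE, t0 = T0) {
  ends <- cumsum(dt_s)
  structure(data.frame(t_start = t0 + c(0, ends[-length(ends)]),
                       t_end = t0 + ends, dt_s = dt_s,
                       distance_m = speed_m_per_min * dt_s / 60,
                       speed_m_per_min = speed_m_per_min,
                       valid = rep_len(valid, length(dt_s))),
            class = c("step_series", "data.frame"))
}

# balanced RCBD frame with 3 treatments x 4 blocks x p periods
rcbd_frame <- function(p = 5) {
  expand.grid(treatment = c("A", "B", "C"), block = 1:4, period = seq_len(p),
              stringsAsFactors = FALSE)
}

write_collar_csv <- function(path, times, lat = NULL, lon = NULL) {
  df <- data.frame(time = times, lat = lat, lon = lon)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
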