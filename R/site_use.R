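# Zone occupancy, Landscape Preference Index, kernel-density hotspot maps.

#' Zone occupancy of a trajectory
#'
#' Fraction of fixes inside each zone (closed convention: fence-line fixes
#' count). At a constant fix rate the fix fraction is the time fraction; for
#' resampled data a dt-weighted variant is available. Overlapping zones are
#' tallied independently, so occupancies of overlapping zones may exceed
#' 100% in total.
#'
#' @param traj planar `gps_trajectory`.
#' @param zones list of `paddock_zone` (buffered already where applicable).
#' @param weight `"fixes"` (count fixes) or `"time"` (weight each fix by the
#'   time to the next fix).
#' @return data.frame with one row per zone: `zone`, `n_inside`, `pct_of_day`
#'   and `hours` (pct/100 x 24).
#' @export
zone_occupancy <- function(traj, zones, weight = c("fixes", "time")) {
  stopifnot(inherits(traj, "gps_trajectory"))
  weight <- match.arg(weight)
  if (!nrow(traj$fixes)) stop("empty trajectory")
  if (traj$crs != "planar") stop("zone_occupancy needs a planar trajectory")
  if (inherits(zones, "paddock_zone")) zones <- list(zones)
  w <- if (weight == "fixes") rep(1, nrow(traj$fixes)) else {
    dt <- as.numeric(diff(traj$fixes$time), units = "secs")
    c(dt, stats::median(dt))
  }
  rows <- lapply(zones, function(z) {
    inside <- point_in_polygon(traj$fixes$x, traj$fixes$y, z$geometry)
    frac <- sum(w[inside]) / sum(w)
    data.frame(zone = z$name, n_inside = sum(inside), pct_of_day = 100 * frac,
               hours = frac * 24, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Landscape Preference Index
#'
#' Ratio of the proportion of time spent in a zone to the proportion of the
#' total area the zone occupies. 1 means use proportional to availability;
#' above 1 means preference.
#'
#' @param time_fraction proportion of time in the zone (0-1).
#' @param area_fraction proportion of the available area (0-1, > 0).
#' @param zone_name optional label.
#' @return one-row data.frame: `zone`, `time_fraction`, `area_fraction`, `lpi`.
#' @export
lpi <- function(time_fraction, area_fraction, zone_name = NA_character_) {
  if (any(area_fraction <= 0) || any(area_fraction > 1))
    stop("area_fraction must be in (0, 1]")
  if (any(time_fraction < 0) || any(time_fraction > 1))
    stop("time_fraction must be in [0, 1]")
  data.frame(zone = zone_name, time_fraction = time_fraction,
             area_fraction = area_fraction, lpi = time_fraction / area_fraction,
             stringsAsFactors = FALSE)
}

#' Kernel density grid of fix locations
#'
#' Smooths fix locations into a density surface (animals per m², scaled so
#' that density times cell area sums to the number of fixes). Fixes are
#' binned to grid cells and the binned counts convolved with the kernel, the
#' standard raster-heatmap construction; spatial resolution is the cell
#' size. The default quartic kernel with a 10 m radius matches the device's
#' sub-10 m location error.
#'
#' @param x,y planar fix coordinates (or pass a `gps_trajectory` as `x`).
#' @param bandwidth_m kernel radius (quartic/Epanechnikov) or standard
#'   deviation (Gaussian, truncated at 4 sigma), meters.
#' @param cell_size_m grid cell edge, meters.
#' @param kernel `"quartic"`, `"gaussian"`, or `"epanechnikov"`.
#' @param margin_m grid margin beyond the fix bounding box; at least the
#'   kernel radius for full mass conservation.
#' @return object of class `density_grid`: `x0`, `y0` (lower-left corner),
#'   `cell_size_m`, and `values` (matrix, rows = y from bottom, cols = x).
#' @export
kernel_density <- function(x, y = NULL, bandwidth_m = 10, cell_size_m = 1,
                           kernel = c("quartic", "gaussian", "epanechnikov"),
                           margin_m = NULL) {
  kernel <- match.arg(kernel)
  if (inherits(x, "gps_trajectory")) {
    y <- x$fixes$y
    x <- x$fixes$x
  }
  stopifnot(length(x) == length(y), length(x) >= 1L, bandwidth_m > 0)
  radius <- if (kernel == "gaussian") 4 * bandwidth_m else bandwidth_m
  if (cell_size_m >= 2 * bandwidth_m)
    warning("cell_size_m >= 2 x bandwidth: kernel is undersampled")
  if (is.null(margin_m)) margin_m <- radius
  x0 <- min(x) - margin_m; y0 <- min(y) - margin_m
  nc <- max(1L, ceiling((max(x) + margin_m - x0) / cell_size_m))
  nr <- max(1L, ceiling((max(y) + margin_m - y0) / cell_size_m))
  ci <- pmin(nc, pmax(1L, floor((x - x0) / cell_size_m) + 1L))
  ri <- pmin(nr, pmax(1L, floor((y - y0) / cell_size_m) + 1L))
  counts <- matrix(0, nr, nc)
  tab <- table(ri + (ci - 1L) * nr)
  counts[as.integer(names(tab))] <- as.numeric(tab)
  m <- ceiling(radius / cell_size_m)
  off <- seq(-m, m)
  vals <- matrix(0, nr, nc)
  h <- bandwidth_m
  for (di in off) {
    rs_dst <- max(1L, 1L + di):min(nr, nr + di)
    rs_src <- rs_dst - di
    if (!length(rs_dst)) next
    for (dj in off) {
      d2 <- (di * cell_size_m)^2 + (dj * cell_size_m)^2
      if (d2 > radius^2) next
      u2 <- d2 / h^2
      w <- switch(kernel,
                  quartic = (3 / (pi * h^2)) * (1 - u2)^2,
                  epanechnikov = (2 / (pi * h^2)) * (1 - u2),
                  gaussian = exp(-u2 / 2) / (2 * pi * h^2))
      cs_dst <- max(1L, 1L + dj):min(nc, nc + dj)
      cs_src <- cs_dst - dj
      if (!length(cs_dst)) next
      vals[rs_dst, cs_dst] <- vals[rs_dst, cs_dst] + w * counts[rs_src, cs_src]
    }
  }
  structure(list(x0 = x0, y0 = y0, cell_size_m = cell_size_m,
                 n_rows = nr, n_cols = nc, n_points = length(x),
                 kernel = kernel, bandwidth_m = bandwidth_m, values = vals),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid %dx%d @ %.1f m, %s kernel h=%.1f m, %d points>\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$kernel, x$bandwidth_m,
              x$n_points))
  invisible(x)
}

#' Total mass of a density grid
#'
#' Sum of density values times cell area; approximately the number of input
#' points when the grid margin covers the kernel radius.
#'
#' @param grid `density_grid`.
#' @return numeric mass.
#' @export
grid_mass <- function(grid) sum(grid$values) * grid$cell_size_m^2

#' Hotspot cells of a density grid
#'
#' Flags cells with density strictly above the given quantile of all cell
#' values — the dark-red cells of a heatmap.
#'
#' @param grid `density_grid`.
#' @param quantile quantile threshold in (0, 1).
#' @return data.frame of flagged cells: `row`, `col`, `x`, `y` (cell
#'   centers), `value`, plus the threshold as an attribute.
#' @export
hotspot_summary <- function(grid, quantile = 0.95) {
  stopifnot(inherits(grid, "density_grid"), quantile > 0, quantile < 1)
  thr <- stats::quantile(grid$values, quantile, names = FALSE)
  idx <- which(grid$values > thr, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1L], col = idx[, 2L],
                    x = grid$x0 + (idx[, 2L] - 0.5) * grid$cell_size_m,
                    y = grid$y0 + (idx[, 1L] - 0.5) * grid$cell_size_m,
                    value = grid$values[idx])
  attr(out, "threshold") <- thr
  out[order(-out$value), , drop = FALSE]
}

#' Write a density grid as an ESRI ASCII raster (.asc)
#'
#' @param grid `density_grid`.
#' @param path output file.
#' @export
write_asc <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.6f", grid$x0),
               sprintf("yllcorner %.6f", grid$y0),
               sprintf("cellsize %.6f", grid$cell_size_m),
               "NODATA_value -9999"), con)
  # ASCII grids run top row first
  for (r in rev(seq_len(grid$n_rows)))
    writeLines(paste(format(grid$values[r, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}
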