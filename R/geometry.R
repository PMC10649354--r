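# Planar geometry primitives: projection, polygon predicates, buffering, areas.
# Everything downstream (geofencing, zone occupancy, KDE grids) works in a
# planar metric frame, either a UTM zone or a local synthetic frame.

#' Construct a planar polygon
#'
#' A simple polygon in a planar metric frame (meters), stored as an exterior
#' ring plus optional holes. Rings are stored open (first vertex not repeated);
#' a closing vertex in the input is dropped.
#'
#' @param coords two-column matrix (or coercible) of exterior vertices, meters.
#' @param holes list of two-column matrices, one per interior ring.
#' @return object of class `planar_polygon`.
#' @export
planar_polygon <- function(coords, holes = list()) {
  norm_ring <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 2L) stop("ring must have two columns (x, y)")
    if (nrow(m) >= 2L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    if (nrow(m) < 3L) stop("polygon ring needs at least 3 distinct vertices")
    dimnames(m) <- list(NULL, c("x", "y"))
    m
  }
  poly <- structure(
    list(exterior = norm_ring(coords), holes = lapply(holes, norm_ring)),
    class = "planar_polygon"
  )
  if (polygon_area(poly) <= 0) stop("degenerate polygon: area must be > 0")
  poly
}

#' @export
print.planar_polygon <- function(x, ...) {
  cat(sprintf("<planar_polygon: %d vertices, %d hole(s), area %.1f m²>\n",
              nrow(x$exterior), length(x$holes), polygon_area(x)))
  invisible(x)
}

#' Axis-aligned rectangle polygon
#'
#' @param xmin,ymin,xmax,ymax corner coordinates, meters.
#' @return `planar_polygon`.
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  planar_polygon(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

.ring_area_signed <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace)
#'
#' Area of a simple polygon, holes subtracted, always positive.
#'
#' @param poly `planar_polygon`.
#' @return area in square meters.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "planar_polygon"))
  a <- abs(.ring_area_signed(poly$exterior))
  if (length(poly$holes))
    a <- a - sum(vapply(poly$holes, function(h) abs(.ring_area_signed(h)), 0))
  a
}

# even-odd crossing test for many points against one ring (vectorized in points)
.ring_crossings <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# TRUE where (px, py) lies on a segment of the ring, within eps
.on_ring <- function(px, py, ring, eps) {
  n <- nrow(ring)
  on <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- ring[j, 1L]; ay <- ring[j, 2L]
    bx <- ring[i, 1L]; by <- ring[i, 2L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      hit <- abs(px - ax) <= eps & abs(py - ay) <= eps
    } else {
      tpar <- ((px - ax) * dx + (py - ay) * dy) / len2
      tpar <- pmin(1, pmax(0, tpar))
      qx <- ax + tpar * dx
      qy <- ay + tpar * dy
      hit <- (px - qx)^2 + (py - qy)^2 <= eps * eps
    }
    on <- on | hit
    j <- i
  }
  on
}

#' Point-in-polygon test (closed convention)
#'
#' Even-odd crossing test with an explicit boundary check: points on the
#' exterior or on a hole boundary count as inside (the closed convention, so
#' fence-line fixes are never lost). Points strictly inside a hole are outside.
#'
#' @param x,y point coordinates, same planar frame as `poly`; vectorized.
#' @param poly `planar_polygon`.
#' @param eps boundary snap tolerance in meters.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  stopifnot(inherits(poly, "planar_polygon"), length(x) == length(y))
  px <- as.numeric(x); py <- as.numeric(y)
  scale <- max(1, max(abs(poly$exterior)))
  tol <- eps * scale
  on_bd <- .on_ring(px, py, poly$exterior, tol)
  inside <- .ring_crossings(px, py, poly$exterior) | on_bd
  for (h in poly$holes) {
    on_h <- .on_ring(px, py, h, tol)
    in_h <- .ring_crossings(px, py, h) & !on_h
    inside <- inside & !in_h
    inside <- inside | on_h   # hole rim is polygon boundary -> inside
  }
  inside
}

.is_convex_ccw <- function(ring) {
  n <- nrow(ring)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  # cross product of consecutive edge vectors
  e1x <- ring[, 1L] - ring[prv, 1L]; e1y <- ring[, 2L] - ring[prv, 2L]
  e2x <- ring[nxt, 1L] - ring[, 1L]; e2y <- ring[nxt, 2L] - ring[, 2L]
  z <- e1x * e2y - e1y * e2x
  all(z >= -1e-9 * max(abs(ring)))
}

#' Buffer a point or convex polygon
#'
#' Outward Minkowski expansion by `radius_m`. A bare point becomes a circle
#' approximated by `n_segments` vertices; a convex polygon gets offset edges
#' joined by vertex arcs (arc vertex count proportional to the turned angle,
#' with `n_segments` corresponding to a full circle). Non-convex polygons are
#' not supported and raise an error; every buffered feature in a paddock
#' layout (shade structure, water trough, rectangular strip) is convex.
#'
#' @param geometry length-2 numeric (point x, y) or a `planar_polygon`.
#' @param radius_m buffer radius in meters, > 0.
#' @param n_segments arc vertices for a full circle (default 64).
#' @return `planar_polygon`.
#' @export
buffer_geometry <- function(geometry, radius_m, n_segments = 64L) {
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0)
    stop("radius_m must be a single positive number")
  n_segments <- max(8L, as.integer(n_segments))
  if (is.numeric(geometry) && length(geometry) == 2L) {
    th <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
    return(planar_polygon(cbind(geometry[1L] + radius_m * cos(th),
                                geometry[2L] + radius_m * sin(th))))
  }
  stopifnot(inherits(geometry, "planar_polygon"))
  if (length(geometry$holes)) stop("buffering polygons with holes is not supported")
  ring <- geometry$exterior
  if (.ring_area_signed(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  if (!.is_convex_ccw(ring)) stop("buffer_geometry supports convex polygons only")
  n <- nrow(ring)
  nxt <- c(2:n, 1L)
  # outward normal of each directed edge i -> nxt(i) for a CCW ring
  ex <- ring[nxt, 1L] - ring[, 1L]; ey <- ring[nxt, 2L] - ring[, 2L]
  elen <- sqrt(ex^2 + ey^2)
  keep <- elen > 0
  if (!all(keep)) {
    ring <- ring[keep, , drop = FALSE]
    return(buffer_geometry(planar_polygon(ring), radius_m, n_segments))
  }
  nx <- ey / elen; ny <- -ex / elen
  ang <- atan2(ny, nx)
  out <- list()
  for (i in seq_len(n)) {
    j <- nxt[i]
    out[[length(out) + 1L]] <- cbind(ring[i, 1L] + radius_m * nx[i],
                                     ring[i, 2L] + radius_m * ny[i])
    out[[length(out) + 1L]] <- cbind(ring[j, 1L] + radius_m * nx[i],
                                     ring[j, 2L] + radius_m * ny[i])
    # arc at vertex j from normal i to normal j, sweeping CCW
    a1 <- ang[i]; a2 <- ang[j]
    da <- (a2 - a1) %% (2 * pi)
    k <- ceiling(n_segments * da / (2 * pi))
    if (k >= 2L) {
      th <- a1 + da * seq_len(k - 1L) / k
      out[[length(out) + 1L]] <- cbind(ring[j, 1L] + radius_m * cos(th),
                                       ring[j, 2L] + radius_m * sin(th))
    }
  }
  planar_polygon(do.call(rbind, out))
}

# ---- transverse Mercator (UTM) ------------------------------------------
# Krueger series on the WGS84 ellipsoid, 6th order in the third flattening;
# forward/inverse agree to well under a millimeter inside a zone.

.tm_consts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    a <- 6378137; f <- 1 / 298.257223563
    n <- f / (2 - f)
    A <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
    alpha <- c(
      n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180 - 127 * n^5 / 288 + 7891 * n^6 / 37800,
      13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440 + 281 * n^5 / 630 - 1983433 * n^6 / 1935360,
      61 * n^3 / 240 - 103 * n^4 / 140 + 15061 * n^5 / 26880 + 167603 * n^6 / 181440,
      49561 * n^4 / 161280 - 179 * n^5 / 168 + 6601661 * n^6 / 7257600,
      34729 * n^5 / 80640 - 3418889 * n^6 / 1995840,
      212378941 * n^6 / 319334400)
    beta <- c(
      n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360 - 81 * n^5 / 512 + 96199 * n^6 / 604800,
      n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440 + 46 * n^5 / 105 - 1118711 * n^6 / 3870720,
      17 * n^3 / 480 - 37 * n^4 / 840 - 209 * n^5 / 4480 + 5569 * n^6 / 90720,
      4397 * n^4 / 161280 - 11 * n^5 / 504 - 830251 * n^6 / 7257600,
      4583 * n^5 / 161280 - 108847 * n^6 / 3991680,
      20648693 * n^6 / 638668800)
    e <- sqrt(f * (2 - f))
    cache <<- list(A = A, alpha = alpha, beta = beta, e = e, k0 = 0.9996,
                   E0 = 5e5, N0_south = 1e7)
    cache
  }
})

#' UTM zone number from longitude
#'
#' @param lon longitude in degrees (vector allowed; the mean is used).
#' @return integer zone 1-60.
#' @export
utm_zone <- function(lon) {
  z <- floor((mean(lon) + 180) / 6) + 1
  as.integer(min(60, max(1, z)))
}

#' Project WGS84 coordinates to UTM meters
#'
#' @param lat,lon degrees, vectorized; `abs(lat)` must be <= 84.
#' @param zone explicit UTM zone number, or `"auto"` to derive it from the
#'   mean longitude.
#' @return list with `x` (easting), `y` (northing), `zone`, `hemisphere`.
#' @export
to_planar <- function(lat, lon, zone = "auto") {
  stopifnot(length(lat) == length(lon))
  if (any(abs(lat) > 84)) stop("latitude outside UTM validity (|lat| > 84)")
  if (any(abs(lon) > 180) || any(abs(lat) > 90)) stop("coordinates out of range")
  if (identical(zone, "auto")) zone <- utm_zone(lon)
  zone <- as.integer(zone)
  south <- mean(lat) < 0
  cc <- .tm_consts()
  lon0 <- (-183 + 6 * zone) * pi / 180
  phi <- lat * pi / 180
  dlam <- lon * pi / 180 - lon0
  e <- cc$e
  t <- sinh(atanh(sin(phi)) - e * atanh(e * sin(phi)))
  xi_p <- atan2(t, cos(dlam))
  eta_p <- asinh(sin(dlam) / sqrt(t^2 + cos(dlam)^2))
  xi <- xi_p; eta <- eta_p
  for (j in 1:6) {
    xi <- xi + cc$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + cc$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  x <- cc$E0 + cc$k0 * cc$A * eta
  y <- cc$k0 * cc$A * xi + if (south) cc$N0_south else 0
  list(x = x, y = y, zone = zone, hemisphere = if (south) "south" else "north")
}

#' Inverse UTM projection back to WGS84 degrees
#'
#' @param x,y easting/northing in meters.
#' @param zone UTM zone number used for the forward projection.
#' @param hemisphere `"north"` or `"south"`.
#' @return list with `lat`, `lon` in degrees.
#' @export
planar_to_geographic <- function(x, y, zone, hemisphere = "north") {
  cc <- .tm_consts()
  hemisphere <- match.arg(hemisphere, c("north", "south"))
  lon0 <- (-183 + 6 * as.integer(zone)) * pi / 180
  xi <- (y - if (hemisphere == "south") cc$N0_south else 0) / (cc$k0 * cc$A)
  eta <- (x - cc$E0) / (cc$k0 * cc$A)
  xi_p <- xi; eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - cc$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - cc$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  tau_p <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  # Newton-solve conformal -> geodetic tangent latitude
  e <- cc$e
  tau <- tau_p
  for (it in 1:8) {
    sig <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    f_tau <- tau * sqrt(1 + sig^2) - sig * sqrt(1 + tau^2) - tau_p
    dtau <- (sqrt((1 + sig^2) * (1 + tau^2)) - sig * tau) *
      (1 - e^2) * sqrt(1 + tau^2) / (1 + (1 - e^2) * tau^2)
    tau <- tau - f_tau / dtau
  }
  list(lat = atan(tau) * 180 / pi, lon = (lam + lon0) * 180 / pi)
}

# ---- zones ---------------------------------------------------------------

#' A named zone of interest within a paddock
#'
#' Wraps a polygon (shade, water trough, bermudagrass strip, weed strip, or a
#' custom area) with its computed area. `buffered` records whether the
#' geometry has already had the 10 m round buffer applied.
#'
#' @param name zone label.
#' @param geometry `planar_polygon`.
#' @param buffered logical flag.
#' @return object of class `paddock_zone`.
#' @export
zone <- function(name, geometry, buffered = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, inherits(geometry, "planar_polygon"))
  structure(list(name = name, geometry = geometry, buffered = isTRUE(buffered),
                 area_m2 = polygon_area(geometry)),
            class = "paddock_zone")
}

#' @export
print.paddock_zone <- function(x, ...) {
  cat(sprintf("<zone '%s'%s: %.1f m²>\n", x$name,
              if (x$buffered) " (buffered)" else "", x$area_m2))
  invisible(x)
}

#' Parse a WKT POLYGON string
#'
#' Accepts `POLYGON ((x y, ...))` with optional hole rings.
#'
#' @param wkt character scalar.
#' @return `planar_polygon`.
#' @export
parse_wkt_polygon <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1L)
  body <- sub("(?i)^\\s*POLYGON\\s*\\(", "", wkt, perl = TRUE)
  if (identical(body, wkt)) stop("not a WKT POLYGON string")
  body <- sub("\\)\\s*$", "", body)
  rings <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1L]]
  parse_ring <- function(r) {
    r <- gsub("[()]", "", r)
    pts <- strsplit(trimws(strsplit(r, ",")[[1L]]), "\\s+")
    do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
  }
  mats <- lapply(rings, parse_ring)
  planar_polygon(mats[[1L]], holes = mats[-1L])
}

.geojson_ring <- function(ring) {
  m <- rbind(ring, ring[1L, , drop = FALSE])
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
}

#' Write zones to a GeoJSON FeatureCollection
#'
#' @param zones list of `paddock_zone`.
#' @param path output file.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(zones, function(z) {
    list(type = "Feature",
         properties = list(name = z$name, buffered = z$buffered),
         geometry = list(type = "Polygon",
                         coordinates = c(list(.geojson_ring(z$geometry$exterior)),
                                         lapply(z$geometry$holes, .geojson_ring))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read zones from a GeoJSON FeatureCollection
#'
#' Polygon features only; the `name` and `buffered` properties are honored.
#'
#' @param path GeoJSON file.
#' @return named list of `paddock_zone`.
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a FeatureCollection")
  zs <- lapply(gj$features, function(f) {
    geom <- f$geometry
    if (!identical(geom$type, "Polygon")) stop("only Polygon features are supported")
    mats <- lapply(geom$coordinates, function(ring)
      do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2]))))
    zone(name = f$properties$name %||% "custom",
         geometry = planar_polygon(mats[[1L]], holes = mats[-1L]),
         buffered = isTRUE(f$properties$buffered))
  })
  names(zs) <- vapply(zs, function(z) z$name, "")
  zs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
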