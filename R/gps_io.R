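# Reading, cleaning, geofencing, and daily segmentation of GPS logger fixes.

#' Construct a GPS trajectory
#'
#' One animal's ordered fix series. Fixes are sorted by time and exact
#' duplicate timestamps are collapsed to the first occurrence (logger files
#' are append-ordered, so the first record is the original fix).
#'
#' @param fixes data.frame with a POSIXct `time` column plus `lat`/`lon`
#'   (geographic) and/or `x`/`y` (planar meters) columns.
#' @param crs `"geographic"` or `"planar"`.
#' @param animal_id,paddock_id,period opaque labels carried through the
#'   pipeline.
#' @return object of class `gps_trajectory`; the cleaning counts are attached
#'   as the `filter_report` attribute.
#' @export
gps_trajectory <- function(fixes, crs = c("geographic", "planar"),
                           animal_id = NA_character_, paddock_id = NA_character_,
                           period = NA) {
  crs <- match.arg(crs)
  stopifnot(is.data.frame(fixes), "time" %in% names(fixes))
  if (!inherits(fixes$time, "POSIXct")) stop("fixes$time must be POSIXct")
  if (crs == "geographic") {
    stopifnot(all(c("lat", "lon") %in% names(fixes)))
    if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180))
      stop("lat/lon out of range")
  } else {
    stopifnot(all(c("x", "y") %in% names(fixes)))
  }
  n_input <- nrow(fixes)
  ord <- order(fixes$time)
  # an out-of-order row is one timestamped before an earlier row
  tn <- as.numeric(fixes$time)
  n_reordered <- if (n_input > 1L)
    sum(tn[-1L] < cummax(tn)[-n_input]) else 0L
  fixes <- fixes[ord, , drop = FALSE]
  dup <- duplicated(fixes$time)
  n_duplicate <- sum(dup)
  fixes <- fixes[!dup, , drop = FALSE]
  rownames(fixes) <- NULL
  structure(
    list(fixes = fixes, crs = crs, animal_id = animal_id,
         paddock_id = paddock_id, period = period),
    filter_report = filter_report(n_input = n_input, n_kept = nrow(fixes),
                                  n_duplicate = n_duplicate,
                                  n_reordered = n_reordered),
    class = "gps_trajectory"
  )
}

#' @export
print.gps_trajectory <- function(x, ...) {
  rng <- range(x$fixes$time)
  cat(sprintf("<gps_trajectory %s/%s: %d fixes (%s), %s .. %s>\n",
              x$paddock_id, x$animal_id, nrow(x$fixes), x$crs,
              format(rng[1]), format(rng[2])))
  invisible(x)
}

#' Number of fixes in a trajectory
#' @param traj `gps_trajectory`.
#' @return integer count.
#' @export
n_fixes <- function(traj) nrow(traj$fixes)

#' Cleaning audit counts
#'
#' @param n_input,n_kept,n_out_of_boundary,n_duplicate,n_reordered,n_bad_rows
#'   counts from a cleaning step. Invariant:
#'   `n_input == n_kept + n_out_of_boundary + n_duplicate`.
#' @return object of class `filter_report`.
#' @export
filter_report <- function(n_input = 0L, n_kept = 0L, n_out_of_boundary = 0L,
                          n_duplicate = 0L, n_reordered = 0L, n_bad_rows = 0L) {
  r <- list(n_input = as.integer(n_input), n_kept = as.integer(n_kept),
            n_out_of_boundary = as.integer(n_out_of_boundary),
            n_duplicate = as.integer(n_duplicate),
            n_reordered = as.integer(n_reordered),
            n_bad_rows = as.integer(n_bad_rows))
  if (r$n_input != r$n_kept + r$n_out_of_boundary + r$n_duplicate)
    stop("filter_report counts do not balance")
  structure(r, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report: %d in, %d kept, %d outside boundary, ",
                     "%d duplicate, %d reordered, %d unparseable>\n"),
              x$n_input, x$n_kept, x$n_out_of_boundary, x$n_duplicate,
              x$n_reordered, x$n_bad_rows), sep = "")
  invisible(x)
}

#' Write a filter report as JSON
#' @param report `filter_report`.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

.parse_times <- function(v, tz, time_format = NULL) {
  if (is.numeric(v)) return(as.POSIXct(v, origin = "1970-01-01", tz = tz))
  v <- as.character(v)
  if (!is.null(time_format)) return(as.POSIXct(v, tz = tz, format = time_format))
  # rows may be individually malformed, so try each format and keep the one
  # that parses the most rows (NA rows are skipped and counted upstream)
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS")
  best <- as.POSIXct(rep(NA_real_, length(v)), origin = "1970-01-01", tz = tz)
  for (f in fmts) {
    cand <- as.POSIXct(strptime(v, format = f, tz = tz))
    if (sum(!is.na(cand)) > sum(!is.na(best))) best <- cand
  }
  best
}

#' Read a GPS logger file into a trajectory
#'
#' Supports delimited logger exports (`dialect = "csv"`, with a configurable
#' column mapping since export formats vary between firmware versions) and
#' GPX 1.1 track points (`dialect = "gpx"`). Rows with an unparseable
#' timestamp or non-numeric coordinates are skipped and counted; duplicate
#' timestamps are collapsed to the first occurrence and out-of-order rows are
#' sorted (counts in the attached `filter_report`).
#'
#' @param path input file.
#' @param dialect `"csv"` or `"gpx"`.
#' @param columns for CSV: named list mapping `time`, and either `lat`/`lon`
#'   or `x`/`y`, to column names in the file.
#' @param coords `"geographic"` (lat/lon degrees) or `"planar"` (x/y meters,
#'   as emitted by the synthetic herd simulator).
#' @param tz timezone used to interpret timestamps without an offset.
#' @param time_format optional `strptime` format override.
#' @param animal_id,paddock_id labels attached to the trajectory.
#' @return `gps_trajectory` with a `filter_report` attribute.
#' @export
read_gps_log <- function(path, dialect = c("csv", "gpx"),
                         columns = list(time = "time", lat = "lat", lon = "lon",
                                        x = "x", y = "y"),
                         coords = c("geographic", "planar"),
                         tz = "UTC", time_format = NULL,
                         animal_id = NA_character_, paddock_id = NA_character_) {
  dialect <- match.arg(dialect)
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gpx") {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
    if (!length(pts)) pts <- xml2::xml_find_all(doc, ".//trkpt")
    if (!length(pts)) stop("no track points in GPX file")
    df <- data.frame(
      time = vapply(pts, function(p) {
        tn <- xml2::xml_find_first(p, ".//g:time", ns)
        if (inherits(tn, "xml_missing")) tn <- xml2::xml_find_first(p, ".//time")
        xml2::xml_text(tn)
      }, ""),
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      stringsAsFactors = FALSE)
    coords <- "geographic"
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(raw)) stop("empty GPS log: ", path)
    need <- if (coords == "geographic") c("time", "lat", "lon") else c("time", "x", "y")
    cols <- vapply(need, function(k) columns[[k]] %||% k, "")
    missing_cols <- cols[!cols %in% names(raw)]
    if (length(missing_cols))
      stop("columns not found in ", path, ": ", paste(missing_cols, collapse = ", "))
    df <- raw[, cols]
    names(df) <- need
    for (k in setdiff(need, "time")) df[[k]] <- suppressWarnings(as.numeric(df[[k]]))
  }
  n_raw <- nrow(df)
  df$time <- .parse_times(df$time, tz, time_format)
  numcols <- setdiff(names(df), "time")
  bad <- is.na(df$time)
  for (k in numcols) bad <- bad | is.na(df[[k]])
  n_bad <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  if (!nrow(df)) stop("no parseable fixes in ", path)
  traj <- gps_trajectory(df, crs = coords, animal_id = animal_id,
                         paddock_id = paddock_id)
  rep0 <- attr(traj, "filter_report")
  attr(traj, "filter_report") <- filter_report(
    n_input = n_raw - n_bad, n_kept = rep0$n_kept, n_duplicate = rep0$n_duplicate,
    n_reordered = rep0$n_reordered, n_bad_rows = n_bad)
  traj
}

#' Project a geographic trajectory to planar UTM meters
#'
#' Already-planar trajectories pass through unchanged, so synthetic data in a
#' local frame never round-trips through the ellipsoid.
#'
#' @param traj `gps_trajectory`.
#' @param zone UTM zone number or `"auto"`.
#' @return planar `gps_trajectory` (with `lat`/`lon` retained if present).
#' @export
project_trajectory <- function(traj, zone = "auto") {
  stopifnot(inherits(traj, "gps_trajectory"))
  if (traj$crs == "planar") return(traj)
  p <- to_planar(traj$fixes$lat, traj$fixes$lon, zone = zone)
  traj$fixes$x <- p$x
  traj$fixes$y <- p$y
  traj$crs <- "planar"
  traj$utm_zone <- p$zone
  traj$hemisphere <- p$hemisphere
  traj
}

#' Geofence a trajectory to a paddock boundary
#'
#' Drops every fix outside the boundary polygon (pathway fixes between the
#' pen and the paddock, GPS noise excursions). Points exactly on the fence
#' line are kept (closed convention). Order is preserved.
#'
#' @param traj planar `gps_trajectory`.
#' @param boundary `planar_polygon` in the same frame.
#' @return list with `trajectory` (filtered) and `report` (`filter_report`).
#' @export
filter_to_boundary <- function(traj, boundary) {
  stopifnot(inherits(traj, "gps_trajectory"), inherits(boundary, "planar_polygon"))
  if (traj$crs != "planar")
    stop("project the trajectory to a planar frame before geofencing")
  keep <- point_in_polygon(traj$fixes$x, traj$fixes$y, boundary)
  out <- traj
  out$fixes <- traj$fixes[keep, , drop = FALSE]
  rownames(out$fixes) <- NULL
  rep <- filter_report(n_input = length(keep), n_kept = sum(keep),
                       n_out_of_boundary = sum(!keep))
  attr(out, "filter_report") <- rep
  list(trajectory = out, report = rep)
}

#' Split a trajectory into local calendar days
#'
#' Splits at local midnight of the study timezone. Each segment carries an
#' `excluded` attribute: days whose fix count falls below `min_coverage`
#' times the expected count (86,400 x the native fix rate) are flagged, which
#' naturally drops collar-recharge days.
#'
#' @param traj `gps_trajectory`.
#' @param tz study timezone (e.g. `"America/Chicago"`).
#' @param min_coverage minimum fraction of expected fixes for a day to count.
#' @param fix_rate_hz native fix rate; `NULL` estimates it from the median
#'   fix spacing.
#' @return named list (ISO date) of daily `gps_trajectory` segments, each
#'   with `excluded` and `coverage` attributes.
#' @export
split_days <- function(traj, tz = "UTC", min_coverage = 0.8, fix_rate_hz = NULL) {
  stopifnot(inherits(traj, "gps_trajectory"))
  tt <- traj$fixes$time
  if (is.null(fix_rate_hz)) {
    dts <- as.numeric(diff(tt), units = "secs")
    fix_rate_hz <- if (length(dts)) 1 / stats::median(dts) else 1
  }
  day <- as.Date(format(tt, tz = tz, format = "%Y-%m-%d"))
  expected <- 86400 * fix_rate_hz
  segs <- lapply(split(seq_along(day), day), function(idx) {
    s <- traj
    s$fixes <- traj$fixes[idx, , drop = FALSE]
    rownames(s$fixes) <- NULL
    cov <- nrow(s$fixes) / expected
    attr(s, "coverage") <- cov
    attr(s, "excluded") <- cov < min_coverage
    attr(s, "date") <- day[idx[1L]]
    s
  })
  segs
}

#' Write a cleaned trajectory as tidy CSV
#'
#' Columns: `animal_id`, `paddock_id`, `iso_time`, then `lat`/`lon` and/or
#' `x`/`y` as available.
#'
#' @param traj `gps_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  f <- traj$fixes
  out <- data.frame(animal_id = traj$animal_id, paddock_id = traj$paddock_id,
                    iso_time = format(f$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    stringsAsFactors = FALSE)
  for (k in c("lat", "lon", "x", "y")) if (k %in% names(f)) out[[k]] <- f[[k]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
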