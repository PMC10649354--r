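# Staged pipeline over a study file tree: simulate -> process -> summarize.
# Each stage is a plain function; the inst/cli script wraps them for shell use.

.log_msg <- function(log_con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized keys (all optional, with package defaults): `min_coverage`,
#' `timezone`, `max_gap_s`, `rest_max_m_per_min`, `travel_min_m_per_min`,
#' `kde` (list: `bandwidth_m`, `cell_size_m`, `kernel`), `seed`, and the
#' `study` block forwarded to [study_config()] scalars.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path) %||% list()
}

#' Simulate a study dataset (pipeline stage)
#'
#' Thin wrapper over [simulate_study()] taking scalar overrides, as the CLI
#' does from its YAML config.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param config named list of [study_config()] scalar overrides
#'   (`n_periods`, `days_per_period`, `fix_rate_hz`, ...).
#' @return manifest from [simulate_study()], invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, config = list()) {
  base_args <- list()
  if (!is.null(config$fix_rate_hz))
    base_args$fix_rate_hz <- config$fix_rate_hz
  base <- do.call(sim_config, base_args)
  sc_args <- config[intersect(names(config),
                              c("n_blocks", "n_periods", "days_per_period",
                                "animals_per_paddock", "day_sd_pp",
                                "paddock_sd_pp", "block_sd_pp"))]
  sc_args$base <- base
  cfg <- do.call(study_config, sc_args)
  simulate_study(cfg, out_dir, seed = seed)
}

#' Process a study file tree into metric tables (pipeline stage)
#'
#' For every collar CSV: ingest, geofence to the paddock boundary, split into
#' local calendar days, and compute daily movement metrics, activity budgets,
#' and zone occupancies. Fixes of each paddock are pooled into one kernel
#' density grid written as an ESRI ASCII raster. Counts and parameters go to
#' `run_log.txt`; cleaning counts to `filter_reports.json`.
#'
#' @param data_dir directory produced by [run_simulate()] (or hand-assembled
#'   with the same layout: `collars/*.csv`, `boundary.geojson`,
#'   `zones.geojson`, `design.csv`).
#' @param out_dir output directory for the metric CSVs and grids.
#' @param min_coverage day-completeness threshold for [split_days()].
#' @param timezone study timezone for day splitting.
#' @param max_gap_s gap threshold for [step_metrics()].
#' @param thresholds `speed_thresholds`.
#' @param kde list of [kernel_density()] parameters.
#' @param on_error `"continue"` (log and skip a bad collar file) or `"abort"`.
#' @return invisibly, list of output paths.
#' @export
run_process <- function(data_dir, out_dir, min_coverage = 0.8, timezone = "UTC",
                        max_gap_s = 300, thresholds = speed_thresholds(),
                        kde = list(bandwidth_m = 10, cell_size_m = 1,
                                   kernel = "quartic"),
                        on_error = c("continue", "abort")) {
  on_error <- match.arg(on_error)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run_log.txt"), "w")
  on.exit(close(log_con))
  boundary <- read_zones_geojson(file.path(data_dir, "boundary.geojson"))[[1L]]$geometry
  zones <- read_zones_geojson(file.path(data_dir, "zones.geojson"))
  files <- list.files(file.path(data_dir, "collars"), pattern = "\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no collar files under ", data_dir)
  .log_msg(log_con, sprintf(
    "processing %d collar file(s); min_coverage=%.2f tz=%s max_gap_s=%d thresholds=(%.2f, %.0f)",
    length(files), min_coverage, timezone, max_gap_s,
    thresholds$rest_max, thresholds$travel_min))
  metrics <- budgets <- occup <- list()
  reports <- list()
  paddock_fixes <- list()
  for (f in files) {
    res <- tryCatch({
      aid <- sub("\\.csv$", "", basename(f))
      traj <- read_gps_log(f, dialect = "csv",
                           columns = list(time = "iso_time", x = "x", y = "y"),
                           coords = "planar", animal_id = aid)
      pid <- utils::read.csv(f, nrows = 1L)$paddock_id
      traj$paddock_id <- as.character(pid)
      fb <- filter_to_boundary(traj, boundary)
      reports[[aid]] <- list(ingest = unclass(attr(traj, "filter_report")),
                             geofence = unclass(fb$report))
      traj <- fb$trajectory
      pidc <- traj$paddock_id
      paddock_fixes[[pidc]] <- rbind(paddock_fixes[[pidc]],
                                     traj$fixes[, c("x", "y")])
      days <- split_days(traj, tz = timezone, min_coverage = min_coverage)
      for (dname in names(days)) {
        seg <- days[[dname]]
        metrics[[length(metrics) + 1L]] <- daily_metrics(seg, max_gap_s = max_gap_s)
        if (!isTRUE(attr(seg, "excluded"))) {
          budgets[[length(budgets) + 1L]] <-
            activity_budget(seg, thresholds, max_gap_s = max_gap_s)
          oc <- zone_occupancy(seg, zones)
          oc <- cbind(data.frame(animal_id = seg$animal_id,
                                 paddock_id = seg$paddock_id,
                                 date = attr(seg, "date")), oc)
          occup[[length(occup) + 1L]] <- oc
        }
      }
      .log_msg(log_con, sprintf("%s: %d fixes kept (%d outside boundary), %d day(s)",
                                aid, n_fixes(traj), fb$report$n_out_of_boundary,
                                length(days)))
      TRUE
    }, error = function(e) {
      if (on_error == "abort") stop(e)
      .log_msg(log_con, sprintf("SKIP %s: %s", basename(f), conditionMessage(e)))
      FALSE
    })
  }
  if (!length(metrics)) stop("no collar file could be processed")
  paths <- list(
    daily_metrics = file.path(out_dir, "daily_metrics.csv"),
    activity_budgets = file.path(out_dir, "activity_budgets.csv"),
    zone_occupancy = file.path(out_dir, "zone_occupancy.csv"),
    filter_reports = file.path(out_dir, "filter_reports.json"))
  utils::write.csv(do.call(rbind, metrics), paths$daily_metrics, row.names = FALSE)
  utils::write.csv(do.call(rbind, budgets), paths$activity_budgets, row.names = FALSE)
  utils::write.csv(do.call(rbind, occup), paths$zone_occupancy, row.names = FALSE)
  jsonlite::write_json(reports, paths$filter_reports, auto_unbox = TRUE)
  grids <- character(0)
  for (pid in names(paddock_fixes)) {
    g <- kernel_density(paddock_fixes[[pid]]$x, paddock_fixes[[pid]]$y,
                        bandwidth_m = kde$bandwidth_m %||% 10,
                        cell_size_m = kde$cell_size_m %||% 1,
                        kernel = kde$kernel %||% "quartic")
    gp <- file.path(out_dir, sprintf("density_%s.asc", pid))
    write_asc(g, gp)
    grids <- c(grids, gp)
    .log_msg(log_con, sprintf("density grid %s: %dx%d cells, mass %.0f",
                              pid, g$n_rows, g$n_cols, grid_mass(g)))
  }
  paths$grids <- grids
  invisible(paths)
}

#' Summarize processed metrics at the treatment x period level
#'
#' Averages tester animals within paddock-days, assigns evaluation periods,
#' reduces to paddock-period means, and runs the fixed-effects RCBD ANOVA
#' per metric. Also writes the derived statistics: percent distance change
#' between the extreme treatments, cross-treatment activity means,
#' zone hours-per-day, and the Landscape Preference Index per zone from the
#' occupancy fractions and the zone/paddock area fractions.
#'
#' @param processed_dir output of [run_process()].
#' @param data_dir study tree with `design.csv`, `periods.csv`,
#'   `zones.geojson`, `boundary.geojson`.
#' @param out_dir where summary CSVs are written.
#' @return invisibly, a list with the treatment tables, ANOVA objects, and
#'   derived statistics.
#' @export
run_summarize <- function(processed_dir, data_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dm <- utils::read.csv(file.path(processed_dir, "daily_metrics.csv"),
                        stringsAsFactors = FALSE)
  if (!nrow(dm)) stop("empty daily metrics")
  ab <- utils::read.csv(file.path(processed_dir, "activity_budgets.csv"),
                        stringsAsFactors = FALSE)
  oc <- utils::read.csv(file.path(processed_dir, "zone_occupancy.csv"),
                        stringsAsFactors = FALSE)
  des <- utils::read.csv(file.path(data_dir, "design.csv"), stringsAsFactors = FALSE)
  per <- utils::read.csv(file.path(data_dir, "periods.csv"), stringsAsFactors = FALSE)
  design <- design_table(des, per)
  dm$date <- as.Date(dm$date); ab$date <- as.Date(ab$date); oc$date <- as.Date(oc$date)
  dm <- dm[!dm$excluded, ]
  # paddock-day means of the headline metrics
  met_cols <- c("distance_m_per_day", "rate_moving_m_per_min",
                "resting_pct", "grazing_pct", "traveling_pct")
  daym <- paddock_daily_means(
    merge(dm, ab[, c("animal_id", "paddock_id", "date",
                     "resting_pct", "grazing_pct", "traveling_pct")],
          by = c("animal_id", "paddock_id", "date")),
    metrics = met_cols)
  daym$period <- assign_period(daym$date, design)
  daym <- daym[!is.na(daym$period), ]
  pd <- unique(des[, c("paddock_id", "block", "treatment")])
  daym <- merge(daym, pd, by = "paddock_id")
  agg <- stats::aggregate(daym[, met_cols],
                          by = daym[, c("paddock_id", "block", "treatment", "period")],
                          FUN = mean)
  tables <- list()
  anovas <- list()
  for (m in met_cols) {
    tp <- treatment_period_table(agg, m)
    tables[[m]] <- tp$treatments
    anovas[[m]] <- tp$anova
    utils::write.csv(tp$treatments,
                     file.path(out_dir, sprintf("treatment_means_%s.csv", m)),
                     row.names = FALSE)
    an_tab <- tp$anova$table
    an_tab$response <- m
    utils::write.csv(an_tab, file.path(out_dir, sprintf("anova_%s.csv", m)),
                     row.names = FALSE)
  }
  # derived statistics
  dmean <- tables$distance_m_per_day
  hi <- dmean$mean[which.max(dmean$mean)]
  lo <- dmean$mean[which.min(dmean$mean)]
  zones <- read_zones_geojson(file.path(data_dir, "zones.geojson"))
  boundary <- read_zones_geojson(file.path(data_dir, "boundary.geojson"))[[1L]]
  occ_mean <- stats::aggregate(pct_of_day ~ zone, data = oc, FUN = mean)
  lpi_rows <- do.call(rbind, lapply(seq_len(nrow(occ_mean)), function(i) {
    zn <- occ_mean$zone[i]
    if (!zn %in% names(zones)) return(NULL)
    lpi(occ_mean$pct_of_day[i] / 100,
        zones[[zn]]$area_m2 / boundary$area_m2, zone_name = zn)
  }))
  derived <- list(
    percent_distance_change = percent_change(hi, lo),
    cross_treatment_means = vapply(
      c("resting_pct", "grazing_pct", "traveling_pct"),
      function(m) cross_treatment_mean(tables[[m]]$mean), 0),
    zone_hours = stats::setNames(frac_to_hours(occ_mean$pct_of_day),
                                 occ_mean$zone),
    lpi = lpi_rows)
  utils::write.csv(
    data.frame(statistic = c("percent_distance_change",
                             paste0("mean_", names(derived$cross_treatment_means)),
                             paste0("hours_", names(derived$zone_hours))),
               value = c(derived$percent_distance_change,
                         derived$cross_treatment_means, derived$zone_hours)),
    file.path(out_dir, "derived_statistics.csv"), row.names = FALSE)
  if (!is.null(lpi_rows))
    utils::write.csv(lpi_rows, file.path(out_dir, "lpi.csv"), row.names = FALSE)
  invisible(list(tables = tables, anovas = anovas, derived = derived,
                 paddock_period = agg))
}
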