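# Temperature-humidity index and climate record handling.

#' Temperature-humidity index
#'
#' `THI = 1.8 Tdb + 32 - (0.55 - 0.0055 RH) * (1.8 Tdb - 26.8)` with dry-bulb
#' temperature in Celsius and relative humidity in percent. At RH = 100 the
#' humidity correction vanishes and THI is the Fahrenheit temperature; at
#' Tdb = 26.8/1.8 (about 14.9 C) THI is independent of RH. Values of 74-79
#' indicate light heat-stress load for beef cattle.
#'
#' @param tdb_c dry-bulb temperature, Celsius; vectorized.
#' @param rh_pct relative humidity, percent (0-100); vectorized.
#' @return THI (unitless).
#' @export
thi <- function(tdb_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE))
    stop("relative humidity must be in [0, 100] percent")
  1.8 * tdb_c + 32 - (0.55 - 0.0055 * rh_pct) * (1.8 * tdb_c - 26.8)
}

#' Read a climate CSV and append THI
#'
#' Expects daily records with date, dry-bulb temperature (Celsius) and
#' relative humidity (percent); column names are configurable.
#'
#' @param path CSV file.
#' @param columns named list mapping `date`, `tdb`, `rh` to file columns.
#' @return data.frame with `date` (Date), `tdb_c`, `rh_pct`, `thi`.
#' @export
read_climate_csv <- function(path, columns = list(date = "date", tdb = "tdb_c",
                                                  rh = "rh_pct")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- vapply(c("date", "tdb", "rh"), function(k) columns[[k]], "")
  miss <- need[!need %in% names(raw)]
  if (length(miss)) stop("climate columns not found: ", paste(miss, collapse = ", "))
  out <- data.frame(date = as.Date(raw[[need[1L]]]),
                    tdb_c = as.numeric(raw[[need[2L]]]),
                    rh_pct = as.numeric(raw[[need[3L]]]))
  out$thi <- thi(out$tdb_c, out$rh_pct)
  out
}
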