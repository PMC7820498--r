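#' Temperature-humidity index
#'
#' THI combining mean daily air temperature (degrees C) and mean daily relative
#' humidity (percent):
#' \deqn{THI = T - (0.55 (1 - RH/100)) (T - 14.4)}
#' At 100\% humidity the index equals the air temperature, and at 14.4 degrees C
#' it equals 14.4 regardless of humidity.
#'
#' @param tavg Mean daily air temperature, degrees C (finite).
#' @param rhavg Mean daily relative humidity, percent, in \[0, 100\].
#' @return Numeric vector of THI values.
#' @examples
#' compute_thi(25, 60)
#' @export
compute_thi <- function(tavg, rhavg) {
  if (any(!is.finite(tavg))) abort("`tavg` must be finite.")
  if (any(!is.finite(rhavg) | rhavg < 0 | rhavg > 100)) {
    abort("`rhavg` must lie in [0, 100] percent.")
  }
  tavg - (0.55 * (1 - rhavg / 100)) * (tavg - 14.4)
}

#' Assign each farm to its nearest weather station
#'
#' @param farms Data frame with columns \code{id, lat, lon} (or \code{id, x, y}
#'   when \code{method = "euclidean"}; \code{lat}/\code{lon} columns are then
#'   interpreted as planar coordinates).
#' @param stations Data frame with the same coordinate columns for stations.
#' @param method \code{"greatcircle"} (haversine distance on latitude/longitude,
#'   km) or \code{"euclidean"} (planar, same units as the coordinates; used by
#'   the synthetic-data generator).
#' @return Tibble \code{farm_id, station_id, distance}. Ties are broken by the
#'   lowest \code{station_id} (after sorting) so the assignment is
#'   deterministic.
#' @export
match_stations <- function(farms, stations, method = c("greatcircle", "euclidean")) {
  method <- match.arg(method)
  stopifnot_cols(farms, c("id", "lat", "lon"), "`farms`")
  stopifnot_cols(stations, c("id", "lat", "lon"), "`stations`")
  if (nrow(stations) < 1L) abort("at least one station is required.")
  bad <- !is.finite(farms$lat) | !is.finite(farms$lon)
  if (any(bad)) {
    abort(sprintf("farm(s) without usable coordinates: %s",
                  paste(farms$id[bad], collapse = ", ")))
  }
  stations <- dplyr::arrange(as_tibble(stations), .data$id)
  D <- if (method == "greatcircle") {
    haversine_km(farms$lat, farms$lon, stations$lat, stations$lon)
  } else {
    outer(seq_len(nrow(farms)), seq_len(nrow(stations)),
          function(i, j) sqrt((farms$lat[i] - stations$lat[j])^2 +
                                (farms$lon[i] - stations$lon[j])^2))
  }
  best <- apply(D, 1L, which.min)  # which.min takes the first (lowest id) on ties
  tibble(
    farm_id = farms$id,
    station_id = stations$id[best],
    distance = D[cbind(seq_len(nrow(farms)), best)]
  )
}

# haversine great-circle distance matrix in km (farms x stations)
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- outer(phi1, phi2, function(a, b) b - a)
  dlam <- outer(lon1 * rad, lon2 * rad, function(a, b) b - a)
  cphi <- outer(cos(phi1), cos(phi2))
  h <- sin(dphi / 2)^2 + cphi * sin(dlam / 2)^2
  # pmin(1, .) would drop the dim attribute of h; keep the matrix shape
  2 * 6371.0088 * asin(pmin(sqrt(h), 1))
}

#' Same-day weather covariate lookup
#'
#' Returns the station value recorded on each queried date; a date absent from
#' the series yields \code{NA} (the record is then flagged for exclusion
#' downstream rather than interpolated).
#'
#' @param weather Data frame with columns \code{station_id, date} and the
#'   requested variable.
#' @param station_id,date Parallel vectors of query keys.
#' @param var Variable to extract (\code{"tavg"}, \code{"thi"}, ...).
#' @return Numeric vector, \code{NA} where the date is missing.
#' @export
covariate_on_day <- function(weather, station_id, date, var = "tavg") {
  stopifnot_cols(weather, c("station_id", "date", var), "`weather`")
  key <- paste(weather$station_id, as.integer(as.Date(weather$date)))
  if (anyDuplicated(key)) abort("duplicate station/date rows in `weather`.")
  q <- paste(station_id, as.integer(as.Date(date)))
  weather[[var]][match(q, key)]
}

#' Week-preceding weather covariate
#'
#' Arithmetic mean of the variable over the 7 calendar days strictly preceding
#' each queried date (\code{d-7 ... d-1}; the test day itself is excluded under
#' the default window). If any of the 7 days is missing from the series the
#' result is \code{NA}.
#'
#' @inheritParams covariate_on_day
#' @param window \code{"preceding"} (default; days \code{d-7..d-1}) or
#'   \code{"including"} (days \code{d-6..d}, i.e. the 6 prior days plus the
#'   test day).
#' @return Numeric vector of 7-day means.
#' @export
covariate_lag7 <- function(weather, station_id, date, var = "tavg",
                           window = c("preceding", "including")) {
  window <- match.arg(window)
  stopifnot_cols(weather, c("station_id", "date", var), "`weather`")
  key <- paste(weather$station_id, as.integer(as.Date(weather$date)))
  if (anyDuplicated(key)) abort("duplicate station/date rows in `weather`.")
  v <- weather[[var]]
  d0 <- as.integer(as.Date(date))
  offs <- if (window == "preceding") -7:-1 else -6:0
  acc <- matrix(NA_real_, length(d0), 7L)
  for (j in seq_along(offs)) {
    q <- paste(station_id, d0 + offs[j])
    acc[, j] <- v[match(q, key)]
  }
  rowMeans(acc)
}

#' Attach weather covariates to test-day records
#'
#' Joins each test-day record to its farm's weather station and adds the
#' same-day and week-preceding air temperature and THI covariates
#' (\code{tavg}, \code{thi}, \code{tavg_lag7}, \code{thi_lag7}). Records whose
#' covariates cannot be resolved (unmatched station or missing weather days)
#' are dropped by default and counted in the attached \code{weather_log}
#' attribute.
#'
#' @param records Test-day records with columns \code{flock_id, test_date}.
#' @param weather Daily weather with columns \code{station_id, date, tavg,
#'   rhavg} (a \code{thi} column is computed if absent).
#' @param station_map Tibble \code{farm_id, station_id} from
#'   \code{\link{match_stations}}; may be \code{NULL} when \code{weather} has a
#'   single station, which is then used for every flock.
#' @param drop Drop unresolved records (default \code{TRUE}); otherwise they
#'   are kept with \code{NA} covariates.
#' @param window Lag-window convention, see \code{\link{covariate_lag7}}.
#' @return The records tibble with four covariate columns added, and an
#'   attribute \code{"weather_log"} with drop counts.
#' @export
add_weather <- function(records, weather, station_map = NULL, drop = TRUE,
                        window = c("preceding", "including")) {
  window <- match.arg(window)
  stopifnot_cols(records, c("flock_id", "test_date"), "`records`")
  stopifnot_cols(weather, c("station_id", "date", "tavg", "rhavg"), "`weather`")
  if (!"thi" %in% names(weather)) {
    weather <- mutate(as_tibble(weather), thi = compute_thi(.data$tavg, .data$rhavg))
  }
  if (is.null(station_map)) {
    sid <- unique(weather$station_id)
    if (length(sid) != 1L) {
      abort("`station_map` is required when `weather` has more than one station.")
    }
    station_map <- tibble(farm_id = unique(records$flock_id), station_id = sid)
  }
  out <- as_tibble(records)
  out$station_id <- station_map$station_id[match(out$flock_id, station_map$farm_id)]
  n_unmatched <- sum(is.na(out$station_id))
  out <- mutate(out,
    tavg = covariate_on_day(weather, .data$station_id, .data$test_date, "tavg"),
    thi = covariate_on_day(weather, .data$station_id, .data$test_date, "thi"),
    tavg_lag7 = covariate_lag7(weather, .data$station_id, .data$test_date, "tavg", window),
    thi_lag7 = covariate_lag7(weather, .data$station_id, .data$test_date, "thi", window)
  )
  n_day <- sum(is.na(out$tavg) & !is.na(out$station_id))
  n_lag <- sum(is.na(out$tavg_lag7) & !is.na(out$tavg))
  unresolved <- is.na(out$tavg) | is.na(out$tavg_lag7) | is.na(out$thi) | is.na(out$thi_lag7)
  log <- list(n_input = nrow(records), n_unmatched_station = n_unmatched,
              n_missing_day = n_day, n_missing_lag7 = n_lag,
              n_dropped = if (drop) sum(unresolved) else 0L,
              n_output = if (drop) sum(!unresolved) else nrow(records))
  if (drop) out <- out[!unresolved, , drop = FALSE]
  attr(out, "weather_log") <- log
  out
}
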