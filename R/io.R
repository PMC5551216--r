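#' Default sky-observation reclassification table
#'
#' Free-text station sky observations mapped to the three-level sky enum
#' used by the transmittance model.
#'
#' @return Named character vector: observation -> sky level.
#' @export
default_sky_reclassification <- function() {
  c("Clear" = "sunny", "Mainly Clear" = "sunny", "Sunny" = "sunny",
    "Partly Cloudy" = "partly_cloudy", "Mainly Cloudy" = "partly_cloudy",
    "Mostly Cloudy" = "cloudy", "Cloudy" = "cloudy", "Overcast" = "cloudy",
    "Rain" = "cloudy", "Thunderstorms" = "cloudy")
}

#' Read hourly station weather from delimited text
#'
#' Expected columns: `station`, `timestamp` (ISO-8601 local clock), `Ta`
#' (C), `RH` (%), `wind` with a `wind_unit` flag (`"ms"` or `"kmh"`), and a
#' free-text `sky_obs` reclassified through `sky_map`.
#'
#' @param path Delimited text file.
#' @param sky_map Named vector mapping observations to sky levels.
#' @param sep Field separator.
#' @param tz Timezone of the local clock (fixed daylight-savings offset).
#' @return A weather `data.frame` (see [weather_record()]).
#' @export
read_weather <- function(path, sky_map = default_sky_reclassification(),
                         sep = ",", tz = "Etc/GMT+4") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("station", "timestamp", "Ta", "RH", "wind", "wind_unit", "sky_obs")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing weather columns: ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(unique(raw$sky_obs), names(sky_map))
  if (length(unknown))
    stop("sky observation(s) not in reclassification table: ",
         paste(sQuote(unknown), collapse = ", "))
  wind10 <- ifelse(raw$wind_unit == "kmh", raw$wind / 3.6, raw$wind)
  weather_record(as.POSIXct(raw$timestamp, tz = tz,
                            tryFormats = c("%Y-%m-%d %H:%M:%S",
                                           "%Y-%m-%dT%H:%M:%S")),
                 raw$Ta, raw$RH, wind10,
                 unname(sky_map[raw$sky_obs]), raw$station)
}

#' Write weather records as delimited text
#'
#' Inverse of [read_weather()]; sky levels are written as observations that
#' the default reclassification maps back to themselves.
#'
#' @param weather Weather `data.frame`.
#' @param path Output path.
#' @export
write_weather <- function(weather, path) {
  obs <- c(sunny = "Clear", partly_cloudy = "Partly Cloudy",
           cloudy = "Cloudy")[weather$sky]
  out <- data.frame(station = weather$station,
                    timestamp = format(weather$timestamp,
                                       "%Y-%m-%d %H:%M:%S"),
                    Ta = weather$Ta, RH = weather$RH,
                    wind = weather$wind10, wind_unit = "ms",
                    sky_obs = unname(obs))
  utils::write.csv(out, path, row.names = FALSE)
}

#' Read pre-tabulated per-tract land-class pixel counts
#'
#' Delimited text with a `tract_id` column, one column per land class, and
#' optionally `polygon_area_ha` and `pixel_edge_m`.
#'
#' @param path Delimited text file.
#' @param sep Field separator.
#' @return List of [tract_composition()] objects, one per row.
#' @export
read_tract_counts <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  cls <- intersect(land_classes(), names(raw))
  if (!length(cls)) stop("no land-class columns found")
  lapply(seq_len(nrow(raw)), function(i) {
    tract_composition(
      tract_id = as.character(raw$tract_id[i]),
      pixel_counts = unlist(raw[i, cls]),
      pixel_edge_m = if ("pixel_edge_m" %in% names(raw))
        raw$pixel_edge_m[i] else 0.6,
      polygon_area_ha = if ("polygon_area_ha" %in% names(raw))
        raw$polygon_area_ha[i] else NA_real_)
  })
}

#' Write a synthetic city as square tract polygons in GeoJSON
#'
#' Each tract becomes a square of its polygon area, laid out on a grid in
#' planar metre coordinates, for exercising the polygon-reading path.
#'
#' @param city Result of [gen_city()].
#' @param path Output GeoJSON path.
#' @export
write_city_geojson <- function(city, path) {
  n <- nrow(city)
  ncol_grid <- ceiling(sqrt(n))
  spacing <- 2 * sqrt(max(city$polygon_area_ha) * 1e4)
  feats <- lapply(seq_len(n), function(i) {
    side <- sqrt(city$polygon_area_ha[i] * 1e4)
    x0 <- ((i - 1) %% ncol_grid) * spacing
    y0 <- ((i - 1) %/% ncol_grid) * spacing
    ring <- list(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
                 c(x0, y0 + side), c(x0, y0))
    list(type = "Feature",
         properties = list(tract_id = city$tract_id[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Drop heat-alert days from the comparison periods
#'
#' Removes rows whose date falls on a heat-alert day unless the day belongs
#' to an EHE period (alert days embedded in Pre/Post spans are excluded
#' from all analyses).
#'
#' @param x `data.frame` with `date` and `period` columns.
#' @param alert_dates Vector of `Date`s classified as heat alerts.
#' @return Filtered `data.frame`.
#' @export
drop_alert_days <- function(x, alert_dates) {
  stopifnot(all(c("date", "period") %in% names(x)))
  keep <- !(as.Date(x$date) %in% as.Date(alert_dates)) | x$period == "EHE"
  x[keep, , drop = FALSE]
}
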