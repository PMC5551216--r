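#' Solar zenith angle
#'
#' Zenith angle of the sun for a site and a vector of timestamps, from the
#' standard fractional-year declination and equation-of-time expansions and
#' the hour angle. Accuracy is well within a degree, which is ample for
#' hourly shortwave modelling.
#'
#' @param latitude Degrees north, in \[-90, 90\].
#' @param longitude Degrees east (negative west).
#' @param time `POSIXct` timestamps. The timezone attribute of the timestamps
#'   is honoured; the study clock is fixed daylight-savings local time
#'   (UTC-4 for Toronto summers).
#' @return Zenith angle in degrees, in \[0, 180\]; values above 90 mean the
#'   sun is below the horizon.
#' @export
solar_zenith <- function(latitude, longitude, time) {
  stopifnot(abs(latitude) <= 90, inherits(time, "POSIXct"))
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1L
  hour_utc <- lt$hour + lt$min / 60 + lt$sec / 3600

  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)

  tst <- hour_utc * 60 + eqtime + 4 * longitude   # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180                # hour angle, radians
  lat <- latitude * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}
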