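#' @keywords internal
"_PACKAGE"

SKY_LEVELS <- c("sunny", "partly_cloudy", "cloudy")

#' Validate / construct hourly weather records
#'
#' @param timestamp `POSIXct` local timestamps (fixed daylight-savings clock).
#' @param Ta Air temperature, C.
#' @param RH Relative humidity, percent.
#' @param wind10 Wind speed at 10 m, m s-1.
#' @param sky Sky condition: `"sunny"`, `"partly_cloudy"` or `"cloudy"`.
#' @param station_id Station label.
#' @return A `data.frame` of hourly weather records.
#' @export
weather_record <- function(timestamp, Ta, RH, wind10, sky,
                           station_id = "station") {
  stopifnot(inherits(timestamp, "POSIXct"))
  if (any(RH < 0 | RH > 100)) stop("RH must be within [0, 100]")
  if (any(wind10 < 0)) stop("wind10 must be >= 0")
  if (!all(sky %in% SKY_LEVELS))
    stop("sky must be one of: ", paste(SKY_LEVELS, collapse = ", "))
  data.frame(station = station_id, timestamp = timestamp,
             Ta = Ta, RH = RH, wind10 = wind10, sky = sky,
             stringsAsFactors = FALSE)
}

#' Wind speed at walker height
#'
#' Converts a 10 m wind speed to the 1.5 m height of a pedestrian using a
#' logarithmic profile over short grass:
#' `u_1.5 = u_10 * ln(1.5 / (0.13 * 0.8)) / 6.65`.
#'
#' @param wind10 Wind speed at 10 m, m s-1 (non-negative).
#' @return Wind speed at 1.5 m, m s-1.
#' @export
wind_at_walker_height <- function(wind10) {
  if (any(wind10 < 0)) stop("wind10 must be >= 0")
  wind10 * log(1.5 / (0.13 * 0.8)) / 6.65
}

#' Atmospheric shortwave transmittance from the sky condition
#'
#' Three-level reclassification of sky observations to bulk shortwave
#' transmittance coefficients: sunny 0.75, partly cloudy 0.40, cloudy 0.25.
#'
#' @param sky Character vector of sky conditions.
#' @return Transmittance coefficients.
#' @export
transmittance_from_sky <- function(sky) {
  tab <- c(sunny = 0.75, partly_cloudy = 0.40, cloudy = 0.25)
  bad <- setdiff(unique(sky), names(tab))
  if (length(bad))
    stop("unknown sky condition ", paste(sQuote(bad), collapse = ", "),
         "; valid values: ", paste(names(tab), collapse = ", "))
  unname(tab[sky])
}

cloud_fraction_from_sky <- function(sky) {
  unname(c(sunny = 0, partly_cloudy = 0.5, cloudy = 1)[sky])
}

#' Saturation vapour pressure (Tetens)
#'
#' @param T_c Temperature, C, in \[-40, 60\].
#' @return Saturation vapour pressure, kPa.
#' @export
saturation_vapor_pressure <- function(T_c) {
  if (any(T_c < -40 | T_c > 60))
    stop("temperature outside [-40, 60] C")
  0.6108 * exp(17.27 * T_c / (T_c + 237.3))
}

#' Ambient vapour pressure from temperature and relative humidity
#'
#' @param Ta Air temperature, C.
#' @param RH Relative humidity, percent.
#' @return Vapour pressure, kPa.
#' @export
air_vapor_pressure <- function(Ta, RH) {
  RH / 100 * saturation_vapor_pressure(Ta)
}

aerodynamic_resistance <- function(wind_walker, person, config) {
  if (any(wind_walker < 0)) stop("wind_walker must be >= 0")
  pmin(config$r_aero_max,
       config$r_aero_coef * sqrt(person$diameter / pmax(wind_walker, 1e-12)))
}

# Shortwave geometry shared by the absorbed-flux and ground-surface models:
# beam normal irradiance through optical air mass 1/cos(Z), a diffuse
# component, the beam interception ratio of a vertical cylinder, and the
# global irradiance reaching the ground of the site (canopy-attenuated beam
# plus sky-view-weighted diffuse).
sw_components <- function(site, zenith, tau, config,
                          constants = phys_constants()) {
  zr <- zenith * pi / 180
  up <- zenith < 90
  m <- ifelse(up, 1 / pmax(cos(zr), 1e-9), Inf)
  tpow <- ifelse(up, tau^m, 0)
  s_perp <- constants$solar_constant * tpow
  beam_horiz <- ifelse(up, s_perp * cos(zr), 0)
  diffuse <- ifelse(up,
                    config$diffuse_frac * (1 - tpow) *
                      constants$solar_constant * cos(zr), 0)
  kcan <- if (isTRUE(site$canopy_overhead)) site$canopy_transmissivity else 1
  k_ground <- kcan * beam_horiz + site$svf * diffuse
  list(s_perp = s_perp, beam_horiz = beam_horiz, diffuse = diffuse,
       kcan = kcan, k_ground = k_ground)
}

#' Shortwave radiation absorbed by the pedestrian
#'
#' Beam irradiance intercepted by a vertical cylinder (attenuated by a
#' deciduous canopy when one is overhead), plus half the sky-view-weighted
#' diffuse irradiance and half the ground-reflected irradiance, scaled by
#' one minus the body albedo. Zero when the sun is below the horizon.
#'
#' @param weather Weather records (only used for recycling length).
#' @param site A [class_site()].
#' @param zenith Solar zenith angle, degrees.
#' @param tau Atmospheric transmittance (0.75 / 0.40 / 0.25).
#' @param person A [person_params()].
#' @param config A [comfa_config()].
#' @param constants [phys_constants()].
#' @return Absorbed shortwave flux, W m-2.
#' @export
shortwave_absorbed <- function(weather, site, zenith, tau,
                               person = person_params(),
                               config = comfa_config(),
                               constants = phys_constants()) {
  sw <- sw_components(site, zenith, tau, config, constants)
  zr <- zenith * pi / 180
  a_cyl <- abs(sin(zr)) / pi + person$diameter / (4 * person$height) *
    pmax(cos(zr), 0)
  beam_on_cyl <- sw$kcan * sw$s_perp * a_cyl
  diff_on_person <- 0.5 * site$svf * sw$diffuse
  refl_on_person <- 0.5 * site$albedo_ground * sw$k_ground
  (1 - person$albedo) * (beam_on_cyl + diff_on_person + refl_on_person)
}

#' Ground surface condition
#'
#' Surface temperature and upwelling longwave flux of the site's ground.
#' Sunlit ground warms above air temperature in proportion to absorbed
#' global shortwave; ground beneath a canopy (or at night) stays at air
#' temperature. The upwelling longwave is the grey-body emission at the
#' surface temperature.
#'
#' @inheritParams shortwave_absorbed
#' @return A list with `T_sf` (C) and `longwave_up` (W m-2), vectorised.
#' @export
ground_condition <- function(weather, site, zenith, tau,
                             config = comfa_config(),
                             constants = phys_constants()) {
  sw <- sw_components(site, zenith, tau, config, constants)
  coef <- if (is.na(site$surface_heating)) config$surf_heat_paved
          else site$surface_heating
  sunlit <- !isTRUE(site$canopy_overhead)
  T_sf <- weather$Ta +
    if (sunlit) coef * (1 - site$albedo_ground) * sw$k_ground else 0
  lw_up <- site$emissivity_ground * constants$sigma * (T_sf + 273.15)^4
  list(T_sf = T_sf, longwave_up = lw_up)
}

#' Longwave exchange of the pedestrian
#'
#' Absorbed longwave combines sky emission (clear-sky emissivity increasing
#' with air temperature, plus a cloud-cover increment), upwelling ground
#' emission, and emission from surrounding vertical surfaces assumed at air
#' temperature, with hemispheric view factors of one half. Emitted longwave
#' is grey-body emission at the clothing surface temperature, a resistive
#' interpolation between skin and air temperature.
#'
#' @param weather Weather records with `Ta`, `RH`, `wind10`, `sky`.
#' @param site A [class_site()].
#' @param ground Result of [ground_condition()].
#' @param person A [person_params()].
#' @param config A [comfa_config()].
#' @param constants [phys_constants()].
#' @param wind_walker Optional wind at 1.5 m; derived from `wind10` if
#'   missing.
#' @return A list with `Labs` and `Lemit`, W m-2.
#' @export
longwave_exchange <- function(weather, site, ground,
                              person = person_params(),
                              config = comfa_config(),
                              constants = phys_constants(),
                              wind_walker = NULL) {
  if (is.null(wind_walker)) wind_walker <- wind_at_walker_height(weather$wind10)
  Ta_k <- weather$Ta + 273.15
  emis_sky <- pmin(1, config$sky_emis_base + config$sky_emis_ta * weather$Ta +
                     config$sky_emis_cloud * cloud_fraction_from_sky(weather$sky))
  L_sky <- emis_sky * constants$sigma * Ta_k^4
  L_walls <- constants$sigma * Ta_k^4
  Labs <- person$emissivity *
    (0.5 * site$svf * L_sky + 0.5 * ground$longwave_up +
       0.5 * (1 - site$svf) * L_walls)

  r_a <- aerodynamic_resistance(wind_walker, person, config)
  T_surface <- (person$T_skin * r_a + weather$Ta * person$r_clothing) /
    (r_a + person$r_clothing)
  Lemit <- person$emissivity * constants$sigma * (T_surface + 273.15)^4
  list(Labs = Labs, Lemit = Lemit)
}

#' Metabolic flux reaching the body surface
#'
#' Metabolic activity minus respiratory evaporative and convective losses.
#' Both loss terms are floored at zero so the flux never exceeds the
#' activity level in very hot, humid air.
#'
#' @param person A [person_params()].
#' @param weather Weather records.
#' @param config A [comfa_config()]; set `respiration = FALSE` to pass the
#'   activity level through unchanged.
#' @return Metabolic flux M, W m-2.
#' @export
metabolic_flux <- function(person, weather, config = comfa_config()) {
  if (!config$respiration) return(rep(person$Ma, nrow(weather)))
  e_air_hpa <- 10 * air_vapor_pressure(weather$Ta, weather$RH)
  e_resp <- pmax(0, config$resp_evap_coef * person$Ma * (44 - e_air_hpa))
  c_resp <- pmax(0, config$resp_conv_coef * person$Ma * (34 - weather$Ta))
  person$Ma - e_resp - c_resp
}

#' Sensible heat flux
#'
#' Resistive convective exchange between the body core and the air through
#' tissue, clothing and the aerodynamic boundary layer. Positive values are
#' a heat loss; the flux changes sign exactly where air temperature reaches
#' core temperature.
#'
#' @param person A [person_params()].
#' @param weather Weather records.
#' @param wind_walker Wind speed at 1.5 m, m s-1.
#' @param config A [comfa_config()].
#' @param constants [phys_constants()].
#' @return Sensible flux H, W m-2.
#' @export
sensible_flux <- function(person, weather, wind_walker,
                          config = comfa_config(),
                          constants = phys_constants()) {
  r_a <- aerodynamic_resistance(wind_walker, person, config)
  constants$rho_cp * (person$T_core - weather$Ta) /
    (config$r_tissue + person$r_clothing + r_a)
}

#' Evaporative heat flux
#'
#' Sweat evaporation driven by the vapour-pressure gradient between
#' saturated skin and the air, across the vapour resistance of clothing and
#' boundary layer, scaled by the wetted skin fraction. Floored at zero (no
#' condensation gain).
#'
#' @inheritParams sensible_flux
#' @return Evaporative flux E, W m-2.
#' @export
evaporative_flux <- function(person, weather, wind_walker,
                             config = comfa_config(),
                             constants = phys_constants()) {
  r_a <- aerodynamic_resistance(wind_walker, person, config)
  r_v <- config$vapor_res_factor * (person$r_clothing + r_a)
  e_skin <- saturation_vapor_pressure(person$T_skin)
  e_air <- air_vapor_pressure(weather$Ta, weather$RH)
  pmax(0, constants$rho_cp / constants$gamma * person$wetness *
         (e_skin - e_air) / r_v)
}

#' Human energy budget
#'
#' Composes the five flux terms into the steady-state pedestrian energy
#' budget `EB = M + R - H - L - E` (W m-2), where R is absorbed short- plus
#' long-wave radiation and L is emitted longwave. Positive budgets indicate
#' net heat gain (thermal stress); the thermally neutral range tops out
#' around +150 W m-2.
#'
#' @param person A [person_params()].
#' @param weather Hourly weather records (see [weather_record()]).
#' @param site A [class_site()].
#' @param config A [comfa_config()].
#' @param constants [phys_constants()]; supplies the site coordinates for
#'   solar geometry.
#' @return A `data.frame` with `timestamp`, the five fluxes `M`, `R`, `H`,
#'   `L`, `E` and their sum `EB`.
#' @export
energy_budget <- function(person, weather, site,
                          config = comfa_config(),
                          constants = phys_constants()) {
  zen <- solar_zenith(constants$latitude, constants$longitude,
                      weather$timestamp)
  tau <- transmittance_from_sky(weather$sky)
  ww <- wind_at_walker_height(weather$wind10)

  K <- shortwave_absorbed(weather, site, zen, tau, person, config, constants)
  grd <- ground_condition(weather, site, zen, tau, config, constants)
  lw <- longwave_exchange(weather, site, grd, person, config, constants, ww)
  M <- metabolic_flux(person, weather, config)
  H <- sensible_flux(person, weather, ww, config, constants)
  E <- evaporative_flux(person, weather, ww, config, constants)

  R <- K + lw$Labs
  L <- lw$Lemit
  data.frame(timestamp = weather$timestamp,
             M = M, R = R, H = H, L = L, E = E,
             EB = M + R - H - L - E)
}

hour_of <- function(timestamp) as.POSIXlt(timestamp)$hour

#' Daytime-window mean energy budget
#'
#' Arithmetic mean of hourly energy budgets over the daytime analysis
#' window: by default the eight hourly stamps 11:00 through 18:00 local
#' daylight-savings time, the hottest part of the day.
#'
#' @param eb Result of [energy_budget()], or any data.frame with
#'   `timestamp` and `EB`.
#' @param window Integer vector `c(first, last)` of hourly stamps included.
#' @return Mean EB over in-window hours, W m-2.
#' @export
daily_mean_eb <- function(eb, window = c(11, 18)) {
  h <- hour_of(eb$timestamp)
  keep <- h >= window[1] & h <= window[2]
  if (!any(keep)) stop("no hours inside the analysis window")
  mean(eb$EB[keep])
}
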