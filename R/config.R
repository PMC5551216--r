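#' Physical constants and site location
#'
#' Fixed physical constants used throughout the energy-budget model, plus the
#' default site coordinates (Toronto) used for solar geometry.
#'
#' @param latitude Site latitude, degrees north.
#' @param longitude Site longitude, degrees east (negative west).
#' @param elevation Site elevation, m above sea level.
#' @return A list with `sigma` (Stefan-Boltzmann, W m-2 K-4), `rho_cp`
#'   (volumetric heat capacity of air, J m-3 K-1), `gamma` (psychrometric
#'   constant, kPa K-1), `solar_constant` (W m-2) and the site coordinates.
#' @export
phys_constants <- function(latitude = 43.6667, longitude = -79.3774,
                           elevation = 112.5) {
  stopifnot(abs(latitude) <= 90)
  list(
    sigma          = 5.67e-8,
    rho_cp         = 1200,
    gamma          = 0.067,
    solar_constant = 1367,
    latitude       = latitude,
    longitude      = longitude,
    elevation      = elevation
  )
}

#' Energy-budget model configuration
#'
#' All tunable constants of the flux sub-models live in this single block so
#' that the calibration of the model against published city-wide energy-budget
#' ranges is transparent. Defaults are the calibrated values used for the
#' bundled Toronto-like study conditions; see the methods vignette for the
#' calibration rationale.
#'
#' @param respiration Include respiratory heat losses in the metabolic flux?
#' @param resp_evap_coef Coefficient of respiratory evaporative loss
#'   (W m-2 per W m-2 of activity per hPa of vapour-pressure deficit from
#'   44 hPa).
#' @param resp_conv_coef Coefficient of respiratory convective loss
#'   (per degree below 34 C).
#' @param diffuse_frac Fraction scaling the diffuse component of solar
#'   irradiance.
#' @param r_aero_coef Coefficient of the boundary-layer aerodynamic
#'   resistance, r_a = coef * sqrt(diameter / wind) (s m-1).
#' @param r_aero_max Cap on aerodynamic resistance in calm air (s m-1).
#' @param r_tissue Body tissue resistance to sensible heat (s m-1);
#'   vasodilated value for hot conditions.
#' @param vapor_res_factor Ratio of vapour to heat resistance for the
#'   clothing + boundary-layer pathway.
#' @param sky_emis_base Clear-sky atmospheric emissivity intercept.
#' @param sky_emis_ta Clear-sky emissivity slope per degree C of air
#'   temperature.
#' @param sky_emis_cloud Emissivity increment at full cloud cover.
#' @param surf_heat_veg Solar heating coefficient of sunlit vegetated ground:
#'   surface excess temperature = coef * (1 - albedo) * K_global (C per W m-2).
#'   Lower than the paved value because transpiration cools vegetation.
#' @param surf_heat_paved Solar heating coefficient of sunlit paved or bare
#'   ground (C per W m-2).
#' @param canopy_svf Default sky-view fraction beneath a tree canopy.
#' @param canopy_transmissivity Fraction of beam shortwave transmitted by a
#'   deciduous canopy in leaf.
#' @return A named list of model constants.
#' @export
comfa_config <- function(respiration = TRUE,
                         resp_evap_coef = 0.0023,
                         resp_conv_coef = 0.0014,
                         diffuse_frac = 0.376,
                         r_aero_coef = 350,
                         r_aero_max = 500,
                         r_tissue = 26.3,
                         vapor_res_factor = 2.209,
                         sky_emis_base = 0.425,
                         sky_emis_ta = 0,
                         sky_emis_cloud = 0.2,
                         surf_heat_veg = 0.0279,
                         surf_heat_paved = 0.0414,
                         canopy_svf = 0.2,
                         canopy_transmissivity = 0.45) {
  cfg <- list(
    respiration = respiration,
    resp_evap_coef = resp_evap_coef,
    resp_conv_coef = resp_conv_coef,
    diffuse_frac = diffuse_frac,
    r_aero_coef = r_aero_coef,
    r_aero_max = r_aero_max,
    r_tissue = r_tissue,
    vapor_res_factor = vapor_res_factor,
    sky_emis_base = sky_emis_base,
    sky_emis_ta = sky_emis_ta,
    sky_emis_cloud = sky_emis_cloud,
    surf_heat_veg = surf_heat_veg,
    surf_heat_paved = surf_heat_paved,
    canopy_svf = canopy_svf,
    canopy_transmissivity = canopy_transmissivity
  )
  stopifnot(all(vapply(cfg[-1], is.numeric, logical(1))),
            canopy_svf >= 0, canopy_svf <= 1,
            canopy_transmissivity >= 0, canopy_transmissivity <= 1)
  cfg
}

#' Person parameters of the modelled pedestrian
#'
#' Metabolic, clothing and geometric constants of the reference pedestrian:
#' a slow walker (2.4 km h-1) dressed for hot weather (T-shirt, shorts,
#' socks, running shoes).
#'
#' @param Ma Metabolic activity, W m-2.
#' @param r_clothing Static clothing resistance to sensible heat, s m-1.
#' @param T_core Body core temperature, C.
#' @param T_skin Mean skin temperature, C.
#' @param albedo Shortwave reflectance of the clothed body surface.
#' @param emissivity Longwave emissivity of the clothed body surface.
#' @param diameter Body cylinder diameter, m.
#' @param height Body height, m.
#' @param wetness Fraction of the skin surface effectively wet with sweat.
#' @return A list of class `person_params`.
#' @export
person_params <- function(Ma = 192, r_clothing = 50, T_core = 37.0,
                          T_skin = 33.0, albedo = 0.37, emissivity = 0.95,
                          diameter = 0.17, height = 1.7, wetness = 0.30) {
  stopifnot(Ma > 0, r_clothing >= 0, T_skin < T_core,
            albedo >= 0, albedo <= 1, emissivity >= 0, emissivity <= 1,
            diameter > 0, height > 0, wetness >= 0, wetness <= 1)
  structure(list(Ma = Ma, r_clothing = r_clothing, T_core = T_core,
                 T_skin = T_skin, albedo = albedo, emissivity = emissivity,
                 diameter = diameter, height = height, wetness = wetness),
            class = "person_params")
}

#' Micro-environment of one land class
#'
#' Radiative and surface properties of a land class treated as a homogeneous
#' micro-environment: sky-view fraction, ground albedo and emissivity, and
#' whether a tree canopy is overhead.
#'
#' @param land_class Label of the land class this site represents.
#' @param svf Sky-view fraction, 0-1.
#' @param albedo_ground Shortwave reflectance of the ground.
#' @param emissivity_ground Longwave emissivity of the ground.
#' @param canopy_overhead Is a tree canopy overhead (beam radiation
#'   attenuated, ground shaded)?
#' @param canopy_transmissivity Beam shortwave transmissivity of the canopy.
#' @param surface_heating Optional solar heating coefficient of the sunlit
#'   ground (C per W m-2); if `NA` the config default for paved ground is
#'   used.
#' @return A list of class `class_site`.
#' @export
class_site <- function(land_class = "GrassShrubAgri", svf = 1,
                       albedo_ground = 0.25, emissivity_ground = 0.95,
                       canopy_overhead = FALSE, canopy_transmissivity = 0.45,
                       surface_heating = NA_real_) {
  stopifnot(svf >= 0, svf <= 1,
            albedo_ground >= 0, albedo_ground <= 1,
            emissivity_ground >= 0, emissivity_ground <= 1,
            canopy_transmissivity >= 0, canopy_transmissivity <= 1,
            is.logical(canopy_overhead))
  structure(list(land_class = land_class, svf = svf,
                 albedo_ground = albedo_ground,
                 emissivity_ground = emissivity_ground,
                 canopy_overhead = canopy_overhead,
                 canopy_transmissivity = canopy_transmissivity,
                 surface_heating = surface_heating),
            class = "class_site")
}

#' Reference (baseline) site: unshaded mown turf grass
#'
#' The baseline environment of the weather stations: no trees, full sky view,
#' grass ground cover with albedo 0.25.
#'
#' @param config Model configuration, see [comfa_config()].
#' @return A `class_site`.
#' @export
baseline_site <- function(config = comfa_config()) {
  class_site(land_class = "GrassShrubAgri", svf = 1, albedo_ground = 0.25,
             emissivity_ground = 0.95, canopy_overhead = FALSE,
             canopy_transmissivity = config$canopy_transmissivity,
             surface_heating = config$surf_heat_veg)
}
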