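# Independent straight-line scalar implementations of the documented flux
# formulas, coded separately from the package internals so the vectorised
# implementation can be checked against them term by term.

oracle_esat <- function(T_c) 0.6108 * exp(17.27 * T_c / (T_c + 237.3))

oracle_metabolic <- function(Ta, RH, Ma = 192, respiration = TRUE,
                             ce = 0.0023, cc = 0.0014) {
  if (!respiration) return(Ma)
  e_air_hpa <- RH / 100 * oracle_esat(Ta) * 10
  e_resp <- max(0, ce * Ma * (44 - e_air_hpa))
  c_resp <- max(0, cc * Ma * (34 - Ta))
  Ma - e_resp - c_resp
}

oracle_raero <- function(u15, d = 0.17, coef = 350, cap = 500) {
  min(cap, coef * sqrt(d / max(u15, 1e-12)))
}

oracle_sensible <- function(Ta, u15, T_core = 37, r_tissue = 26.3,
                            r_clothing = 50, d = 0.17, coef = 350,
                            cap = 500) {
  1200 * (T_core - Ta) /
    (r_tissue + r_clothing + oracle_raero(u15, d, coef, cap))
}

oracle_evaporative <- function(Ta, RH, u15, wetness = 0.30, T_skin = 33,
                               r_clothing = 50, vrf = 2.209, d = 0.17,
                               coef = 350, cap = 500) {
  r_v <- vrf * (r_clothing + oracle_raero(u15, d, coef, cap))
  e_air <- RH / 100 * oracle_esat(Ta)
  max(0, 1200 / 0.067 * wetness * (oracle_esat(T_skin) - e_air) / r_v)
}

oracle_shortwave <- function(zen_deg, tau, svf, albedo_ground,
                             canopy = FALSE, tcan = 0.45,
                             albedo_person = 0.37, d = 0.17, h = 1.7,
                             diffuse_frac = 0.376) {
  if (zen_deg >= 90) return(0)
  z <- zen_deg * pi / 180
  m <- 1 / max(cos(z), 1e-9)
  s_perp <- 1367 * tau^m
  beam_h <- s_perp * cos(z)
  diffuse <- diffuse_frac * (1 - tau^m) * 1367 * cos(z)
  kcan <- if (canopy) tcan else 1
  a_cyl <- sin(z) / pi + d / (4 * h) * cos(z)
  k_ground <- kcan * beam_h + svf * diffuse
  (1 - albedo_person) * (kcan * s_perp * a_cyl + 0.5 * svf * diffuse +
                           0.5 * albedo_ground * k_ground)
}

oracle_ground <- function(Ta, zen_deg, tau, svf, albedo_ground,
                          emissivity_ground, heat_coef, canopy = FALSE,
                          tcan = 0.45, diffuse_frac = 0.376) {
  if (zen_deg >= 90) {
    k_ground <- 0
  } else {
    z <- zen_deg * pi / 180
    m <- 1 / max(cos(z), 1e-9)
    kcan <- if (canopy) tcan else 1
    k_ground <- kcan * 1367 * tau^m * cos(z) +
      svf * diffuse_frac * (1 - tau^m) * 1367 * cos(z)
  }
  T_sf <- if (canopy) Ta else Ta + heat_coef * (1 - albedo_ground) * k_ground
  list(T_sf = T_sf,
       longwave_up = emissivity_ground * 5.67e-8 * (T_sf + 273.15)^4)
}

oracle_longwave <- function(Ta, sky, svf, longwave_up, u15,
                            emissivity_person = 0.95, T_skin = 33,
                            r_clothing = 50, sky_base = 0.425,
                            sky_ta = 0, sky_cloud = 0.2, d = 0.17,
                            coef = 350, cap = 500) {
  cloud <- c(sunny = 0, partly_cloudy = 0.5, cloudy = 1)[[sky]]
  emis_sky <- min(1, sky_base + sky_ta * Ta + sky_cloud * cloud)
  Ta_k <- Ta + 273.15
  labs <- emissivity_person * (0.5 * svf * emis_sky * 5.67e-8 * Ta_k^4 +
                                 0.5 * longwave_up +
                                 0.5 * (1 - svf) * 5.67e-8 * Ta_k^4)
  r_a <- oracle_raero(u15, d, coef, cap)
  t_sur <- (T_skin * r_a + Ta * r_clothing) / (r_a + r_clothing)
  lemit <- emissivity_person * 5.67e-8 * (t_sur + 273.15)^4
  list(Labs = labs, Lemit = lemit)
}

# one-row weather frame for scalar flux checks
one_hour <- function(Ta, RH, wind10, sky = "sunny",
                     time = as.POSIXct("2005-06-28 13:00:00",
                                       tz = "Etc/GMT+4")) {
  weather_record(time, Ta, RH, wind10, sky)
}

# random weather + site generator for property tests
random_cases <- function(n) {
  data.frame(
    Ta = runif(n, 5, 42),
    RH = runif(n, 10, 100),
    wind10 = runif(n, 0, 12),
    sky = sample(c("sunny", "partly_cloudy", "cloudy"), n, replace = TRUE),
    zen = runif(n, 0, 110),
    svf = runif(n, 0, 1),
    alb_g = runif(n, 0.05, 0.4),
    emis_g = runif(n, 0.7, 0.98),
    canopy = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
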