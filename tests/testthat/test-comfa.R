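test_that("walker-height wind conversion is the documented log-profile factor", {
  expect_identical(wind_at_walker_height(0), 0)
  expect_equal(wind_at_walker_height(1), 0.4013, tolerance = 1e-3 / 0.4013)
  expect_equal(wind_at_walker_height(4.2), 1.686, tolerance = 1e-2 / 1.686)
  expect_error(wind_at_walker_height(-0.1), ">= 0")

  # strict linearity: output/input constant for all positive inputs
  u <- withr::with_seed(1, runif(200, 1e-6, 50))
  expect_equal(wind_at_walker_height(u) / u,
               rep(log(1.5 / 0.104) / 6.65, 200), tolerance = 1e-12)
})

test_that("sky conditions map to the three transmittance coefficients", {
  expect_identical(transmittance_from_sky(c("sunny", "partly_cloudy",
                                            "cloudy")),
                   c(0.75, 0.40, 0.25))
  expect_error(transmittance_from_sky("drizzle"), "sunny.*partly_cloudy")
})

test_that("saturation vapour pressure follows Tetens and is monotone", {
  expect_equal(saturation_vapor_pressure(0), 0.611, tolerance = 0.01 / 0.611)
  expect_equal(saturation_vapor_pressure(33), 5.03, tolerance = 0.1 / 5.03)
  expect_true(saturation_vapor_pressure(30) > saturation_vapor_pressure(20))
  expect_error(saturation_vapor_pressure(-50), "outside")
})

test_that("solar zenith behaves at reference geometries", {
  # sun overhead at the equator at an equinox local solar noon
  eq <- as.POSIXct("2005-03-20 12:00:00", tz = "UTC") + (-120:120) * 60
  expect_lt(min(solar_zenith(0, 0, eq)), 1)

  # Toronto summer solstice minimum zenith near latitude - declination
  day <- as.POSIXct("2005-06-21 00:00:00", tz = "Etc/GMT+4") +
    seq(0, 24 * 3600, by = 300)
  zen <- solar_zenith(43.6667, -79.3774, day)
  expect_equal(min(zen), 20.2, tolerance = 1 / 20.2)

  # mid-latitude June midnight: sun below the horizon
  expect_gt(solar_zenith(43.6667, -79.3774,
                         as.POSIXct("2005-06-21 00:00:00",
                                    tz = "Etc/GMT+4")), 90)

  # symmetry about solar noon to within equation-of-time drift
  noon <- day[which.min(zen)]
  expect_equal(solar_zenith(43.6667, -79.3774, noon - 2 * 3600),
               solar_zenith(43.6667, -79.3774, noon + 2 * 3600),
               tolerance = 0.1)
})

test_that("absorbed shortwave: night, canopy attenuation and tau monotonicity", {
  w <- one_hour(30, 50, 4)
  site <- class_site(svf = 1, albedo_ground = 0.25)
  expect_identical(shortwave_absorbed(w, site, 95, 0.75), 0)

  # beam-only geometry: canopy/open ratio is exactly the transmissivity
  beam_site <- function(can) class_site(svf = 0, albedo_ground = 0,
                                        canopy_overhead = can,
                                        canopy_transmissivity = 0.45)
  k_open <- shortwave_absorbed(w, beam_site(FALSE), 30, 0.75)
  k_can <- shortwave_absorbed(w, beam_site(TRUE), 30, 0.75)
  expect_equal(k_can / k_open, 0.45, tolerance = 1e-12)

  for (zen in c(15, 45, 75)) {
    ks <- vapply(c(0.25, 0.40, 0.75), function(tau)
      shortwave_absorbed(w, site, zen, tau), numeric(1))
    expect_true(all(diff(ks) > 0))
  }
})

test_that("ground surface cools as albedo rises; emission follows grey-body law", {
  w <- one_hour(29.7, 53.8, 4.2)
  cfg <- comfa_config()
  albs <- seq(0.05, 0.4, by = 0.05)
  lw <- vapply(albs, function(a) {
    s <- class_site(albedo_ground = a, emissivity_ground = 0.9)
    ground_condition(w, s, 30, 0.75, cfg)$longwave_up
  }, numeric(1))
  expect_true(all(diff(lw) < 0))

  # concrete swap: cooler, less-emissive surface than asphalt in full sun
  asph <- ground_condition(w, site_for_class("Road"), 30, 0.75, cfg)
  conc <- ground_condition(w, site_for_class("Road", cooling_scenario(0.1)),
                           30, 0.75, cfg)
  expect_lt(conc$T_sf, asph$T_sf)
  expect_lt(conc$longwave_up, asph$longwave_up)
})

test_that("longwave exchange: zero-emissivity person, Ta response, skin-limit emission", {
  w <- one_hour(29.7, 53.8, 4.2)
  site <- baseline_site()
  grd <- ground_condition(w, site, 30, 0.75)
  p0 <- person_params(emissivity = 0)
  lw0 <- longwave_exchange(w, site, grd, p0)
  expect_identical(c(lw0$Labs, lw0$Lemit), c(0, 0))

  # absorbed longwave increases with air temperature, all else equal
  labs <- vapply(c(20, 25, 30, 35), function(ta) {
    wt <- one_hour(ta, 50, 4.2)
    g <- ground_condition(wt, site, 30, 0.75)
    longwave_exchange(wt, site, g, person_params())$Labs
  }, numeric(1))
  expect_true(all(diff(labs) > 0))

  # air at skin temperature: clothing surface sits at 33 C exactly
  w33 <- one_hour(33, 50, 4.2)
  g33 <- ground_condition(w33, site, 30, 0.75)
  lw33 <- longwave_exchange(w33, site, g33, person_params())
  expect_equal(lw33$Lemit, 0.95 * 5.67e-8 * 306.15^4, tolerance = 1e-12)
})

test_that("metabolic flux: pass-through, monotonicity and oracle value", {
  p <- person_params()
  off <- comfa_config(respiration = FALSE)
  expect_identical(metabolic_flux(p, one_hour(29.7, 53.8, 4.2), off), 192)

  m_cool_dry <- metabolic_flux(p, one_hour(20, 30, 4))
  m_hot_wet <- metabolic_flux(p, one_hour(32, 80, 4))
  expect_gt(m_hot_wet, m_cool_dry)

  expect_equal(metabolic_flux(p, one_hour(29.7, 53.8, 4.2)),
               oracle_metabolic(29.7, 53.8), tolerance = 1e-12)
  # losses never push the flux above the activity level in extreme air
  expect_lte(metabolic_flux(p, one_hour(42, 95, 2)), 192)
})

test_that("sensible flux changes sign at core temperature and falls with Ta", {
  p <- person_params()
  expect_equal(sensible_flux(p, one_hour(37, 50, 4.2), 1.69), 0,
               tolerance = 1e-12)
  h <- vapply(c(20, 23.3, 29.7, 33, 36.9, 37.1, 40), function(ta)
    sensible_flux(p, one_hour(ta, 50, 4.2), 1.69), numeric(1))
  expect_true(all(diff(h) < 0))
  expect_true(all(h[1:5] > 0) && all(h[6:7] < 0))
  expect_gt(sensible_flux(p, one_hour(23.3, 56.4, 4.2), 1.69),
            sensible_flux(p, one_hour(29.7, 53.8, 4.2), 1.69))
  expect_equal(sensible_flux(p, one_hour(29.7, 53.8, 4.2), 1.69),
               oracle_sensible(29.7, 1.69), tolerance = 1e-12)
})

test_that("evaporative flux: saturated limit, humidity response, oracle value", {
  p <- person_params()
  # air vapour pressure above saturation at skin temperature: no evaporation
  expect_identical(evaporative_flux(p, one_hour(36, 100, 4.2), 1.69), 0)
  # the printed EHE humidity gives a weaker skin-air gradient than the Pre one
  e_ehe <- evaporative_flux(p, one_hour(29.7, 53.8, 4.2), 1.69)
  e_pre <- evaporative_flux(p, one_hour(23.3, 56.4, 4.2), 1.69)
  expect_lt(e_ehe, e_pre)
  expect_equal(e_ehe, oracle_evaporative(29.7, 53.8, 1.69), tolerance = 1e-12)
  # drying the air at fixed temperature increases the flux
  e_rh <- vapply(c(95, 70, 45, 20), function(rh)
    evaporative_flux(p, one_hour(29.7, rh, 4.2), 1.69), numeric(1))
  expect_true(all(diff(e_rh) > 0))
})

test_that("energy budget is the exact five-term composition", {
  p <- person_params()
  w <- gen_weather(weather_gen_spec(), seed = 11)[1:100, ]
  eb <- energy_budget(p, w, baseline_site())
  expect_equal(eb$EB, eb$M + eb$R - eb$H - eb$L - eb$E, tolerance = 1e-15)

  # matches separately invoked component operations
  cons <- phys_constants()
  zen <- solar_zenith(cons$latitude, cons$longitude, w$timestamp)
  tau <- transmittance_from_sky(w$sky)
  ww <- wind_at_walker_height(w$wind10)
  site <- baseline_site()
  grd <- ground_condition(w, site, zen, tau)
  lw <- longwave_exchange(w, site, grd, p)
  manual <- metabolic_flux(p, w) +
    shortwave_absorbed(w, site, zen, tau, p) + lw$Labs -
    sensible_flux(p, w, ww) - lw$Lemit - evaporative_flux(p, w, ww)
  expect_equal(eb$EB, manual, tolerance = 1e-12)
})

test_that("degenerate parameters drive the budget to zero", {
  p <- person_params(Ma = 1e-9, albedo = 1, emissivity = 0, wetness = 0,
                     T_core = 37, T_skin = 33)
  w <- one_hour(37, 50, 4.2,
                time = as.POSIXct("2005-06-28 01:00:00", tz = "Etc/GMT+4"))
  eb <- energy_budget(p, w, baseline_site(), comfa_config(respiration = FALSE))
  expect_lt(abs(eb$EB), 1e-6)
})

test_that("the reference environment is hotter under heat-event weather", {
  p <- person_params()
  day <- as.POSIXct("2005-06-28 00:00:00", tz = "Etc/GMT+4") + (0:23) * 3600
  ehe <- weather_record(day, 29.7, 53.8, 4.2, "sunny")
  pre <- weather_record(day, 23.3, 56.4, 4.2, "sunny")
  expect_gt(daily_mean_eb(energy_budget(p, ehe, baseline_site())),
            daily_mean_eb(energy_budget(p, pre, baseline_site())))
})

test_that("daytime-window mean uses only the eight in-window stamps", {
  day <- as.POSIXct("2005-06-28 00:00:00", tz = "Etc/GMT+4") + (0:23) * 3600
  eb <- data.frame(timestamp = day, EB = seq_along(day))
  # stamps 11..18 carry values 12..19
  expect_identical(daily_mean_eb(eb), mean(12:19))
  win_only <- eb[12:19, ]
  win_only$EB <- 1:8
  expect_identical(daily_mean_eb(win_only), 4.5)
  same <- win_only; same$EB <- rep(7.5, 8)
  expect_identical(daily_mean_eb(same), 7.5)
  expect_error(daily_mean_eb(eb[1:5, ]), "window")
})
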