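#' Study calendar of heat events
#'
#' The four multi-day extreme-heat-event (EHE) periods used as the study
#' conditions (2005, 2006 and two 2010 events), each flanked by its Pre and
#' Post comparison days. Day counts per period net of removed heat-alert
#' days are 25 Pre, 18 EHE and 26 Post.
#'
#' @return `data.frame` with `event`, `date`, `period`.
#' @export
study_calendar <- function() {
  ev <- list(
    list(event = "2005",  start = "2005-06-27", ehe = 4L, pre = 6L, post = 7L),
    list(event = "2006",  start = "2006-07-29", ehe = 5L, pre = 5L, post = 7L),
    list(event = "2010a", start = "2010-05-24", ehe = 4L, pre = 7L, post = 5L),
    list(event = "2010b", start = "2010-08-29", ehe = 5L, pre = 7L, post = 7L)
  )
  do.call(rbind, lapply(ev, function(e) {
    s <- as.Date(e$start)
    dates <- c(seq(s - e$pre, by = "day", length.out = e$pre),
               seq(s, by = "day", length.out = e$ehe),
               seq(s + e$ehe, by = "day", length.out = e$post))
    data.frame(event = e$event, date = dates,
               period = rep(c("Pre", "EHE", "Post"),
                            c(e$pre, e$ehe, e$post)),
               stringsAsFactors = FALSE)
  }))
}

#' Weather generator specification
#'
#' Period-level targets for the seeded synthetic weather generator. The
#' default targets are the study's daytime-window summary statistics:
#' air temperature 23.3 +/- 3.8 (Pre), 29.7 +/- 2.5 (EHE), 23.3 +/- 3.9
#' (Post) C; relative humidity 56.4 / 53.8 / 56.0 %; wind 4.2 / 4.2 / 5.2
#' m s-1; with 25 / 18 / 26 days across four heat events.
#'
#' Day-level draws are moment-matched to the targets (the finite synthetic
#' sample reproduces the target mean and SD exactly) and sky-condition
#' draws are stratified to the exact category proportions; both behaviours
#' can be disabled for purely random sampling.
#'
#' @param ta_mean,ta_sd,rh_mean,rh_sd,wind_mean,wind_sd Per-period targets,
#'   named `Pre`, `EHE`, `Post`.
#' @param sky_probs Sky-condition probabilities (shared across periods so
#'   the period contrast is attributable to the printed weather
#'   differences).
#' @param diurnal_amp_ta Diurnal half-amplitude of air temperature, C.
#' @param diurnal_amp_rh Diurnal half-amplitude of relative humidity, %.
#' @param calendar Day calendar (`date`, `period`, `event`), default
#'   [study_calendar()].
#' @param match_moments Moment-match day-level draws to targets?
#' @param stratify_sky Stratify sky draws to exact proportions?
#' @param two_stations Emulate two correlated stations whose inputs are
#'   averaged?
#' @param station_cor Day-level between-station correlation.
#' @return A list of class `weather_gen_spec`.
#' @export
weather_gen_spec <- function(ta_mean = c(Pre = 23.3, EHE = 29.7, Post = 23.3),
                             ta_sd = c(Pre = 3.8, EHE = 2.5, Post = 3.9),
                             rh_mean = c(Pre = 56.4, EHE = 53.8, Post = 56.0),
                             rh_sd = c(Pre = 16.0, EHE = 9.9, Post = 14.8),
                             wind_mean = c(Pre = 4.2, EHE = 4.2, Post = 5.2),
                             wind_sd = c(Pre = 1.3, EHE = 1.5, Post = 2.2),
                             sky_probs = c(sunny = 0.5, partly_cloudy = 0.3,
                                           cloudy = 0.2),
                             diurnal_amp_ta = 7,
                             diurnal_amp_rh = 8,
                             calendar = study_calendar(),
                             match_moments = TRUE,
                             stratify_sky = TRUE,
                             two_stations = TRUE,
                             station_cor = 0.9) {
  stopifnot(all(ta_sd >= 0), all(rh_sd >= 0), all(wind_sd >= 0),
            abs(sum(sky_probs) - 1) < 1e-9, all(sky_probs >= 0),
            all(c("date", "period") %in% names(calendar)),
            station_cor > -1, station_cor < 1)
  structure(list(ta_mean = ta_mean, ta_sd = ta_sd, rh_mean = rh_mean,
                 rh_sd = rh_sd, wind_mean = wind_mean, wind_sd = wind_sd,
                 sky_probs = sky_probs, diurnal_amp_ta = diurnal_amp_ta,
                 diurnal_amp_rh = diurnal_amp_rh, calendar = calendar,
                 match_moments = match_moments, stratify_sky = stratify_sky,
                 two_stations = two_stations, station_cor = station_cor),
            class = "weather_gen_spec")
}

# day-level draw around (mean, sd), optionally rescaled so the sample mean
# and SD equal the targets exactly
# Day-level anomalies. Moment matching uses a stratified normal sample
# (fixed standardized quantiles) so every finite sample reproduces the
# target mean, SD and distribution shape; quantiles are dealt evenly
# across the heat events (balanced by rank, shuffled within event) so no
# event is systematically hotter than another. Without matching, plain
# i.i.d. normal draws.
draw_day_values <- function(n, mean, sd, match, groups = NULL) {
  if (sd == 0) return(rep(mean, n))
  if (!match) return(stats::rnorm(n, mean, sd))
  if (n == 1) return(mean)
  z <- stats::qnorm(stats::ppoints(n))
  z <- sort(z / stats::sd(z))
  if (is.null(groups)) return(mean + sd * sample(z))
  groups <- as.character(groups)
  sizes <- table(groups)
  # even spread of ranks per group: group g takes positions (k - 0.5)/n_g
  pos <- unlist(lapply(names(sizes), function(g)
    (seq_len(sizes[[g]]) - 0.5) / sizes[[g]]))
  lab <- rep(names(sizes), sizes)
  ord <- order(pos, stats::runif(length(pos)))
  lab_seq <- lab[ord]                    # group label per ascending quantile
  out <- numeric(n)
  for (g in names(sizes)) {
    vals <- z[lab_seq == g]
    out[groups == g] <- sample(vals)
  }
  mean + sd * out
}

# Fixed scramble permutation of 1..n (independent of the caller's RNG
# stream) used to pair the humidity and wind quantiles with the
# temperature ranks: the joint day-level sample is then a fixed Latin
# hypercube whose calendar assignment alone is randomised by the seed.
fixed_scramble <- function(n, salt) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20170714 + salt)
  sample.int(n)
}

stratified_sky <- function(n, probs) {
  counts <- floor(probs * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- probs * n - counts
    add <- order(-frac)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  sample(rep(names(probs), counts))
}

#' Generate hourly synthetic weather
#'
#' Seeded hourly weather over the study calendar: day-level means are drawn
#' per period around the spec targets, hourly values follow a sinusoidal
#' diurnal cycle peaking mid-afternoon (anchored so the 11:00-18:00 window
#' mean equals the day value), humidity runs in anti-phase, wind is held at
#' its day value, and sky conditions are drawn per hour. Two correlated
#' stations are emulated and averaged (input averaging precedes the
#' energy-budget computation).
#'
#' @param spec A [weather_gen_spec()].
#' @param seed Integer seed; identical seeds give identical series.
#' @param average_stations Return the averaged series (default) or both
#'   station series.
#' @return A weather `data.frame` (see [weather_record()]) with added
#'   `date`, `hour`, `period`, `event` columns.
#' @export
gen_weather <- function(spec = weather_gen_spec(), seed = NULL,
                        average_stations = TRUE) {
  run <- function() {
    cal <- spec$calendar
    nd <- nrow(cal)
    per <- cal$period
    ta_d <- rh_d <- wi_d <- numeric(nd)
    dta <- drh <- dwi <- numeric(nd)
    # inter-station day-level offset giving the requested correlation
    dfac <- 2 * sqrt((1 - spec$station_cor) / (1 + spec$station_cor))
    evday <- if ("event" %in% names(cal)) cal$event else rep("all", nd)
    for (p in unique(per)) {
      i <- which(per == p)
      ta_d[i] <- draw_day_values(length(i), spec$ta_mean[[p]],
                                 spec$ta_sd[[p]], spec$match_moments,
                                 evday[i])
      if (spec$match_moments && length(i) > 1) {
        zq <- stats::qnorm(stats::ppoints(length(i)))
        zq <- zq / stats::sd(zq)
        rk <- rank(ta_d[i], ties.method = "first")
        rh_d[i] <- spec$rh_mean[[p]] +
          spec$rh_sd[[p]] * zq[fixed_scramble(length(i), 1L)[rk]]
        wi_d[i] <- spec$wind_mean[[p]] +
          spec$wind_sd[[p]] * zq[fixed_scramble(length(i), 2L)[rk]]
      } else {
        rh_d[i] <- draw_day_values(length(i), spec$rh_mean[[p]],
                                   spec$rh_sd[[p]], spec$match_moments,
                                   evday[i])
        wi_d[i] <- draw_day_values(length(i), spec$wind_mean[[p]],
                                   spec$wind_sd[[p]], spec$match_moments,
                                   evday[i])
      }
      if (spec$two_stations) {
        dta[i] <- stats::rnorm(length(i), 0, dfac * spec$ta_sd[[p]])
        drh[i] <- stats::rnorm(length(i), 0, dfac * spec$rh_sd[[p]])
        dwi[i] <- stats::rnorm(length(i), 0, dfac * spec$wind_sd[[p]])
      }
    }
    rh_d <- pmin(100, pmax(3, rh_d))
    wi_d <- pmax(0.2, wi_d)

    hours <- 0:23
    phase <- cos(2 * pi * (hours - 15) / 24)
    cwin <- mean(phase[hours >= 11 & hours <= 18])

    idx <- rep(seq_len(nd), each = 24)
    hh <- rep(hours, nd)
    ph <- rep(phase, nd) - cwin

    # sky draws stratified by period, event and hour-of-day so the category
    # proportions are realised as exactly as integer rounding allows within
    # every solar-geometry stratum
    sky <- character(length(idx))
    ev <- if ("event" %in% names(cal)) cal$event else rep("all", nd)
    for (p in unique(per)) {
      if (spec$stratify_sky) {
        for (e in unique(ev[per == p])) {
          for (h in hours) {
            j <- which(per[idx] == p & ev[idx] == e & hh == h)
            sky[j] <- stratified_sky(length(j), spec$sky_probs)
          }
        }
      } else {
        j <- which(per[idx] == p)
        sky[j] <- sample(names(spec$sky_probs), length(j), replace = TRUE,
                         prob = spec$sky_probs)
      }
    }

    mk <- function(offset, station) {
      Ta <- ta_d[idx] + offset * dta[idx] + spec$diurnal_amp_ta * ph
      RH <- pmin(100, pmax(2, rh_d[idx] + offset * drh[idx] -
                             spec$diurnal_amp_rh * ph))
      wind <- pmax(0.05, wi_d[idx] + offset * dwi[idx])
      ts <- as.POSIXct(paste(cal$date[idx], sprintf("%02d:00:00", hh)),
                       tz = "Etc/GMT+4")
      cbind(weather_record(ts, Ta, RH, wind, sky, station),
            data.frame(date = cal$date[idx], hour = hh,
                       period = per[idx], event = ev[idx],
                       stringsAsFactors = FALSE))
    }
    if (!spec$two_stations) return(mk(0, "station"))
    if (average_stations) mk(0, "mean") else
      rbind(mk(+0.5, "A"), mk(-0.5, "B"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' City generator specification
#'
#' @param n_tracts Number of census tracts (study city: 544).
#' @param alpha Dirichlet concentration over the eight land classes,
#'   controlling the tract-to-tract land-cover mixture.
#' @param area_range_ha Uniform range of tract areas, ha.
#' @param pixel_edge_m Raster pixel edge, m.
#' @return A list of class `city_gen_spec`.
#' @export
city_gen_spec <- function(n_tracts = 544,
                          alpha = c(TreeCanopy = 3, GrassShrub = 4,
                                    BareEarth = 0.5, Water = 0.4,
                                    Building = 2.5, Road = 2,
                                    OtherPaved = 2.5, Agriculture = 0.3),
                          area_range_ha = c(20, 150),
                          pixel_edge_m = 0.6) {
  stopifnot(n_tracts >= 1, all(alpha >= 0), sum(alpha) > 0,
            identical(sort(names(alpha)), sort(land_classes())),
            area_range_ha[1] > 0, pixel_edge_m > 0)
  structure(list(n_tracts = n_tracts, alpha = alpha[land_classes()],
                 area_range_ha = area_range_ha,
                 pixel_edge_m = pixel_edge_m),
            class = "city_gen_spec")
}

#' Generate a synthetic city of tract land-cover compositions
#'
#' Per-tract class proportions are Dirichlet draws; integer pixel counts
#' are multinomial at the tract's pixel total, so counts are exactly
#' consistent with tract area.
#'
#' @param spec A [city_gen_spec()].
#' @param seed Integer seed.
#' @return `data.frame` with `tract_id`, `polygon_area_ha`,
#'   `pixel_edge_m`, and one count column per land class.
#' @export
gen_city <- function(spec = city_gen_spec(), seed = NULL) {
  run <- function() {
    n <- spec$n_tracts
    k <- length(spec$alpha)
    g <- matrix(stats::rgamma(n * k, shape = rep(spec$alpha, each = n)),
                nrow = n)
    props <- g / rowSums(g)
    area <- stats::runif(n, spec$area_range_ha[1], spec$area_range_ha[2])
    npx <- round(area * 1e4 / spec$pixel_edge_m^2)
    counts <- t(vapply(seq_len(n),
                       function(i) stats::rmultinom(1, npx[i], props[i, ])[, 1],
                       numeric(k)))
    colnames(counts) <- land_classes()
    cbind(data.frame(tract_id = sprintf("CT%04d", seq_len(n)),
                     polygon_area_ha = npx * spec$pixel_edge_m^2 / 1e4,
                     pixel_edge_m = spec$pixel_edge_m,
                     stringsAsFactors = FALSE),
          as.data.frame(counts))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' EMR call generator specification
#'
#' @param baseline_rate Baseline daily call rate per tract (> 0).
#' @param beta Log-link coefficient on the standardised tract pEB.
#' @param heat_fraction Binomial thinning probability for the heat-related
#'   subset.
#' @param dispersion Negative-binomial size parameter; `NULL` for Poisson.
#' @return A list of class `call_gen_spec`.
#' @export
call_gen_spec <- function(baseline_rate = 2, beta = 0.5,
                          heat_fraction = 0.35, dispersion = NULL) {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  stopifnot(heat_fraction >= 0, heat_fraction <= 1)
  structure(list(baseline_rate = baseline_rate, beta = beta,
                 heat_fraction = heat_fraction, dispersion = dispersion),
            class = "call_gen_spec")
}

#' Generate daily EMR call counts coupled to tract energy budgets
#'
#' Daily calls per tract-day follow
#' `calls ~ Poisson(baseline * exp(beta * z(pEB)))` where `z` standardises
#' pEB across the table; the heat-related subset is a binomial thinning.
#'
#' @param peb `data.frame` with `tract_id`, `date`, `peb`.
#' @param spec A [call_gen_spec()].
#' @param seed Integer seed.
#' @return Input table plus `total_calls` and `heat_related_calls`.
#' @export
gen_emr_calls <- function(peb, spec = call_gen_spec(), seed = NULL) {
  stopifnot(all(c("tract_id", "date", "peb") %in% names(peb)))
  run <- function() {
    s <- stats::sd(peb$peb)
    z <- if (is.na(s) || s == 0) rep(0, nrow(peb)) else
      (peb$peb - mean(peb$peb)) / s
    lambda <- spec$baseline_rate * exp(spec$beta * z)
    if (!all(is.finite(lambda))) stop("non-finite call rates")
    calls <- if (is.null(spec$dispersion)) stats::rpois(length(lambda), lambda)
             else stats::rnbinom(length(lambda), mu = lambda,
                                 size = spec$dispersion)
    heat <- stats::rbinom(length(calls), calls, spec$heat_fraction)
    out <- peb
    out$total_calls <- calls
    out$heat_related_calls <- heat
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
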