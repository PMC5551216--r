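#' Daily-window energy budgets per land class
#'
#' Computes the daytime-window mean energy budget of each included land
#' class for every day of an hourly weather series. Tract pEBs are then
#' proportion-weighted mixtures of these columns, which makes whole-city
#' pEB computation cheap.
#'
#' @inheritParams tract_peb
#' @return `data.frame` with `date` and one `eb_<class>` column per
#'   included class.
#' @export
class_daily_eb <- function(weather, person = person_params(),
                           scenario = NULL, config = comfa_config(),
                           constants = phys_constants(), window = c(11, 18)) {
  cls <- interest_classes()
  h <- hour_of(weather$timestamp)
  keep <- h >= window[1] & h <= window[2]
  if (!any(keep)) stop("no hours inside the analysis window")
  day <- as.Date(weather$timestamp[keep], tz = attr(weather$timestamp, "tzone"))
  eb <- sapply(cls, function(cl) {
    site <- site_for_class(cl, scenario, config)
    energy_budget(person, weather, site, config, constants)$EB[keep]
  })
  agg <- aggregate(eb, by = list(date = day), FUN = mean)
  names(agg) <- c("date", paste0("eb_", cls))
  agg
}

pipeline_defaults <- function() {
  list(
    weather_spec = weather_gen_spec(),
    city_spec = city_gen_spec(),
    call_spec = call_gen_spec(),
    person = person_params(),
    config = comfa_config(),
    constants = phys_constants(),
    window = c(11, 18),
    canopy_targets = study_canopy_targets(),
    study_tracts = study_tract_proportions(),
    call_mapping = example_canopy_call_mapping(),
    alert_dates = as.Date(character())
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> extract -> energy budget -> scenario -> stats
#' deterministically for a given seed, and writes machine-readable result
#' tables: the by-period baseline energy budget summary, per-event-year
#' correlation tables between city-wide call counts and weather/energy
#' variables, the existing-versus-proposed design comparison for the two
#' bundled study-tract stand-ins, and the city ranking change.
#'
#' @param config Named list overriding any element of the pipeline
#'   defaults (`weather_spec`, `city_spec`, `call_spec`, `person`,
#'   `config`, `constants`, `window`, `canopy_targets`, `study_tracts`,
#'   `call_mapping`, `alert_dates`), or a path to a YAML file with scalar
#'   overrides.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param outdir Output directory for delimited result tables (`NULL` to
#'   skip writing).
#' @param quiet Suppress stage log messages.
#' @return (Invisibly) a list with `weather`, `city`, `period_beb`,
#'   `period_test`, `correlations`, `comparison`, `ranking`, `calls`.
#' @export
run_pipeline <- function(config = list(), seed = 1, outdir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults()
  bad <- setdiff(names(config), names(cfg))
  if (length(bad)) stop("unknown pipeline config entries: ",
                        paste(bad, collapse = ", "))
  cfg[names(config)] <- config   # shallow override: entries are whole specs
  say <- function(...) if (!quiet) message("[heatbudget] ", ...)
  say("seed = ", seed)

  say("stage simulate: weather")
  weather <- gen_weather(cfg$weather_spec, seed = seed + 1L)
  weather <- drop_alert_days(weather, cfg$alert_dates)

  say("stage simulate: city (", cfg$city_spec$n_tracts, " tracts)")
  city <- gen_city(cfg$city_spec, seed = seed + 2L)
  cls8 <- land_classes()
  props <- t(apply(as.matrix(city[, cls8]), 1, proportions_of_interest))
  colnames(props) <- interest_classes()

  say("stage ebudget: baseline and per-class budgets")
  beb <- baseline_eb(weather, cfg$person, cfg$config, cfg$constants,
                     cfg$window)
  daymeta <- unique(weather[, c("date", "period", "event")])
  beb <- merge(beb, daymeta, by = "date")
  period_test <- period_compare(beb$beb, beb$period)
  period_beb <- period_test$summary

  class_eb <- class_daily_eb(weather, cfg$person, NULL, cfg$config,
                             cfg$constants, cfg$window)
  ebm <- as.matrix(class_eb[, paste0("eb_", interest_classes())])
  tract_day_peb <- do.call(rbind, lapply(seq_len(nrow(city)), function(i) {
    data.frame(tract_id = city$tract_id[i], date = class_eb$date,
               peb = drop(ebm %*% props[i, ]), stringsAsFactors = FALSE)
  }))

  say("stage simulate: EMR calls")
  calls <- gen_emr_calls(tract_day_peb, cfg$call_spec, seed = seed + 3L)

  say("stage stats: correlation tables")
  citywide <- aggregate(cbind(total_calls, heat_related_calls) ~ date,
                        data = calls, FUN = sum)
  dayagg <- aggregate(cbind(Ta) ~ date, data = weather, FUN = mean)
  names(dayagg)[2] <- "ta_24h"
  win <- weather[weather$hour >= cfg$window[1] & weather$hour <= cfg$window[2], ]
  dayagg$ta_8h <- aggregate(Ta ~ date, data = win, FUN = mean)$Ta
  dayagg$tmax_24h <- aggregate(Ta ~ date, data = weather, FUN = max)$Ta
  dayagg$tmin_24h <- aggregate(Ta ~ date, data = weather, FUN = min)$Ta
  daily <- Reduce(function(a, b) merge(a, b, by = "date"),
                  list(citywide, dayagg, beb))
  vars <- c(beb = "beb", ta_24h = "ta_24h", ta_8h = "ta_8h",
            tmax_24h = "tmax_24h", tmin_24h = "tmin_24h")
  correlations <- do.call(rbind, lapply(unique(daily$event), function(ev) {
    d <- daily[daily$event == ev, ]
    do.call(rbind, lapply(c("total_calls", "heat_related_calls"),
                          function(outc) {
      do.call(rbind, lapply(names(vars), function(v) {
        r <- correlate(d[[outc]], d[[vars[v]]], policy = "pearson")
        data.frame(event = ev, outcome = outc, variable = v,
                   r = r$estimate, p = r$p, n = r$n,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  ehe_weather <- weather[weather$period == "EHE", ]
  comparison <- ranking <- NULL
  if (nrow(ehe_weather) == 0) {
    warning("no EHE days in the generated weather; design comparison skipped")
  } else {
    say("stage scenario: cooling designs for study tracts")
    rows <- list()
    rank_rows <- list()
    ehe_class_eb <- class_eb[class_eb$date %in% unique(ehe_weather$date), ]
    ebm_ehe <- as.matrix(ehe_class_eb[, paste0("eb_", interest_classes())])
    city_peb_ehe <- drop(props %*% colMeans(ebm_ehe))
    for (tr in names(cfg$study_tracts)) {
      p0 <- cfg$study_tracts[[tr]]
      scen <- cooling_scenario(cfg$canopy_targets[[tr]])
      p1 <- apply_design(p0, scen)
      ex <- tract_peb(p0, ehe_weather, cfg$person, NULL, cfg$config,
                      cfg$constants, cfg$window)
      pr <- tract_peb(p1, ehe_weather, cfg$person, scen, cfg$config,
                      cfg$constants, cfg$window)
      cmp <- compare_designs(ex, pr)
      red <- emr_reduction_estimate(p0[["TreeCanopy"]], p1[["TreeCanopy"]],
                                    cfg$call_mapping)
      rows[[tr]] <- data.frame(
        tract = tr, n_days = cmp$n,
        existing_peb = mean(ex$peb), proposed_peb = mean(pr$peb),
        mean_delta = cmp$mean_delta, sd_delta = cmp$sd_delta,
        paired_t = cmp$t, p = cmp$p,
        emr_reduction_pct = red, stringsAsFactors = FALSE)
      pool <- c(city_peb_ehe, mean(ex$peb))
      names(pool) <- c(city$tract_id, tr)
      rk0 <- rank_tracts(pool)
      pool[tr] <- mean(pr$peb)
      rk1 <- rank_tracts(pool)
      rank_rows[[tr]] <- data.frame(
        tract = tr, n_tracts = length(pool),
        rank_existing = rk0$rank[rk0$tract_id == tr],
        pct_existing = rk0$percentile[rk0$tract_id == tr],
        rank_proposed = rk1$rank[rk1$tract_id == tr],
        pct_proposed = rk1$percentile[rk1$tract_id == tr],
        stringsAsFactors = FALSE)
    }
    comparison <- do.call(rbind, rows)
    ranking <- do.call(rbind, rank_rows)
  }

  out <- list(weather = weather, city = city, period_beb = period_beb,
              period_test = period_test, correlations = correlations,
              comparison = comparison, ranking = ranking, calls = calls)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(period_beb, file.path(outdir, "period_beb.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    if (!is.null(comparison))
      utils::write.csv(comparison, file.path(outdir, "design_comparison.csv"),
                       row.names = FALSE)
    if (!is.null(ranking))
      utils::write.csv(ranking, file.path(outdir, "ranking.csv"),
                       row.names = FALSE)
    say("tables written to ", normalizePath(outdir))
  }
  invisible(out)
}
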