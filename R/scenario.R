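#' Cooling-design scenario specification
#'
#' A design intervention on a tract: raise tree-canopy cover to a target
#' fraction (debiting source classes pro-rata) and/or swap paved-surface
#' material properties (e.g. asphaltic concrete, albedo 0.10 / emissivity
#' 0.90, replaced by cementic concrete, albedo 0.30 / emissivity 0.75).
#'
#' @param canopy_target_fraction Target Tree Canopy proportion, 0-1 (or
#'   `NULL` for no canopy change).
#' @param surface_swaps Named list: class -> `c(albedo, emissivity)` new
#'   ground properties.
#' @param canopy_source_classes Classes whose area is converted to canopy,
#'   debited pro-rata.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(canopy_target_fraction = NULL,
                          surface_swaps = list(),
                          canopy_source_classes = c("GrassShrubAgri",
                                                    "BareEarth", "Road",
                                                    "OtherPaved")) {
  if (!is.null(canopy_target_fraction))
    stopifnot(canopy_target_fraction >= 0, canopy_target_fraction <= 1)
  bad <- setdiff(names(surface_swaps), interest_classes())
  if (length(bad))
    stop("surface swaps reference non-included classes: ",
         paste(bad, collapse = ", "))
  stopifnot(all(canopy_source_classes %in% interest_classes()))
  structure(list(canopy_target_fraction = canopy_target_fraction,
                 surface_swaps = surface_swaps,
                 canopy_source_classes = canopy_source_classes),
            class = "scenario_spec")
}

#' Standard "cooling" scenario
#'
#' Canopy raised to a target plus replacement of asphalt by light concrete
#' on roads and other paved surfaces.
#'
#' @param canopy_target_fraction Target canopy proportion.
#' @return A [scenario_spec()].
#' @export
cooling_scenario <- function(canopy_target_fraction) {
  scenario_spec(
    canopy_target_fraction = canopy_target_fraction,
    surface_swaps = list(Road = c(albedo = 0.30, emissivity = 0.75),
                         OtherPaved = c(albedo = 0.30, emissivity = 0.75))
  )
}

#' Micro-environment for a land class
#'
#' Default radiative/surface properties for each included land class,
#' optionally modified by a scenario's surface swaps: Tree Canopy sits under
#' a deciduous canopy with reduced sky view; grass is the reference turf
#' surface; bare earth is a light unvegetated surface; roads and other paved
#' surfaces default to asphaltic concrete.
#'
#' @param land_class One of [interest_classes()].
#' @param scenario Optional [scenario_spec()] providing surface swaps.
#' @param config A [comfa_config()].
#' @return A [class_site()].
#' @export
site_for_class <- function(land_class, scenario = NULL,
                           config = comfa_config()) {
  if (!land_class %in% interest_classes())
    stop("no micro-environment defined for class ", sQuote(land_class),
         " (excluded from the energy-budget weighting)")
  site <- switch(land_class,
    TreeCanopy = class_site("TreeCanopy", svf = config$canopy_svf,
                            albedo_ground = 0.25, emissivity_ground = 0.95,
                            canopy_overhead = TRUE,
                            canopy_transmissivity = config$canopy_transmissivity,
                            surface_heating = config$surf_heat_veg),
    GrassShrubAgri = baseline_site(config),
    BareEarth = class_site("BareEarth", svf = 1, albedo_ground = 0.30,
                           emissivity_ground = 0.92,
                           surface_heating = config$surf_heat_paved),
    Road = class_site("Road", svf = 1, albedo_ground = 0.10,
                      emissivity_ground = 0.90,
                      surface_heating = config$surf_heat_paved),
    OtherPaved = class_site("OtherPaved", svf = 1, albedo_ground = 0.10,
                            emissivity_ground = 0.90,
                            surface_heating = config$surf_heat_paved)
  )
  if (!is.null(scenario) && land_class %in% names(scenario$surface_swaps)) {
    swap <- scenario$surface_swaps[[land_class]]
    site$albedo_ground <- unname(swap[["albedo"]])
    site$emissivity_ground <- unname(swap[["emissivity"]])
  }
  site
}

#' Apply a design scenario to a tract composition
#'
#' Raises the Tree Canopy proportion to the scenario target by debiting the
#' source classes pro-rata; total proportion mass is conserved. Surface
#' swaps do not alter proportions (they alter the class micro-environments
#' via [site_for_class()]).
#'
#' @param props Named proportions over [interest_classes()], summing to 1.
#' @param scenario A [scenario_spec()].
#' @return Modified proportions, summing to 1.
#' @export
apply_design <- function(props, scenario) {
  stopifnot(abs(sum(props) - 1) < 1e-9)
  target <- scenario$canopy_target_fraction
  if (is.null(target)) return(props)
  cur <- if ("TreeCanopy" %in% names(props)) unname(props["TreeCanopy"]) else 0
  if (target < cur - 1e-12)
    stop("canopy target (", target, ") below current canopy cover (", cur, ")")
  src <- intersect(scenario$canopy_source_classes, names(props))
  avail <- sum(props[src])
  need <- target - cur
  if (need > avail + 1e-12)
    stop("insufficient source area to reach the canopy target")
  if (avail > 0) props[src] <- props[src] * (avail - need) / avail
  props["TreeCanopy"] <- target
  props
}

#' Tract-level predicted energy budget (pEB)
#'
#' Treats each land class as a homogeneous micro-environment occupied in
#' proportion to its area: the hourly tract pEB is the composition-weighted
#' mixture of the per-class energy budgets, and the daily value is the mean
#' over the daytime window.
#'
#' @param props Named class proportions (sum to 1 within 1e-9).
#' @param weather Hourly weather records.
#' @param person A [person_params()].
#' @param scenario Optional [scenario_spec()] whose surface swaps apply to
#'   the class micro-environments (proportions are NOT modified here; use
#'   [apply_design()] first for canopy changes).
#' @param config,constants Model configuration and constants.
#' @param window Daytime window of hourly stamps.
#' @return `data.frame` with `date`, `peb` and per-class daily mean EB
#'   columns `eb_<class>`.
#' @export
tract_peb <- function(props, weather, person = person_params(),
                      scenario = NULL, config = comfa_config(),
                      constants = phys_constants(), window = c(11, 18)) {
  if (abs(sum(props) - 1) > 1e-9)
    stop("class proportions must sum to 1 (got ", signif(sum(props), 8), ")")
  cls <- names(props)
  eb_cls <- sapply(cls, function(cl) {
    site <- site_for_class(cl, scenario, config)
    energy_budget(person, weather, site, config, constants)$EB
  })
  eb_cls <- matrix(eb_cls, nrow = nrow(weather),
                   dimnames = list(NULL, cls))
  peb_hour <- drop(eb_cls %*% unname(props))

  h <- hour_of(weather$timestamp)
  keep <- h >= window[1] & h <= window[2]
  if (!any(keep)) stop("no hours inside the analysis window")
  day <- as.Date(weather$timestamp[keep], tz = attr(weather$timestamp, "tzone"))
  agg <- aggregate(cbind(peb_hour[keep], eb_cls[keep, , drop = FALSE]),
                   by = list(date = day), FUN = mean)
  names(agg) <- c("date", "peb", paste0("eb_", cls))
  agg
}

#' Baseline energy budget (bEB) series
#'
#' Daily-window mean energy budget in the reference environment of the
#' weather stations: an unshaded mown turf grass field (full sky view,
#' ground albedo 0.25, no trees).
#'
#' @inheritParams tract_peb
#' @return `data.frame` with `date` and `beb`.
#' @export
baseline_eb <- function(weather, person = person_params(),
                        config = comfa_config(),
                        constants = phys_constants(), window = c(11, 18)) {
  res <- tract_peb(c(GrassShrubAgri = 1), weather, person, NULL,
                   config, constants, window)
  data.frame(date = res$date, beb = res$peb)
}

#' Compare existing and proposed designs
#'
#' Per-day pEB differences (proposed minus existing) with a within-tract
#' paired t-test. A degenerate zero-variance difference series is flagged
#' and reported with p = 1 rather than failing.
#'
#' @param existing,proposed `data.frame`s from [tract_peb()] over the same
#'   days.
#' @return A list with the per-day `deltas`, `mean_delta`, `sd_delta`, the
#'   paired `t`, two-sided `p`, `n`, and `zero_variance` flag.
#' @export
compare_designs <- function(existing, proposed) {
  if (nrow(existing) != nrow(proposed) ||
      !all(as.character(existing$date) == as.character(proposed$date)))
    stop("existing and proposed series must cover the same days")
  delta <- proposed$peb - existing$peb
  n <- length(delta)
  m <- mean(delta)
  s <- stats::sd(delta)
  if (is.na(s) || s < 1e-12) {
    return(list(deltas = data.frame(date = existing$date, delta = delta),
                mean_delta = m, sd_delta = if (is.na(s)) 0 else s,
                t = NA_real_, p = 1, n = n, zero_variance = TRUE))
  }
  tt <- stats::t.test(proposed$peb, existing$peb, paired = TRUE)
  list(deltas = data.frame(date = existing$date, delta = delta),
       mean_delta = m, sd_delta = s,
       t = unname(tt$statistic), p = tt$p.value, n = n,
       zero_variance = FALSE)
}

#' Rank tracts by predicted energy budget
#'
#' Descending rank (1 = hottest); ties share the smaller rank. The
#' percentile convention is `(N - rank) / N * 100`, so the hottest tract of
#' a large city sits near the 100th percentile.
#'
#' @param peb_by_tract Named numeric vector of tract pEB values.
#' @return `data.frame` with `tract_id`, `peb`, `rank`, `percentile`.
#' @export
rank_tracts <- function(peb_by_tract) {
  if (!length(peb_by_tract)) stop("need at least one tract")
  n <- length(peb_by_tract)
  r <- rank(-peb_by_tract, ties.method = "min")
  data.frame(tract_id = if (is.null(names(peb_by_tract)))
               as.character(seq_len(n)) else names(peb_by_tract),
             peb = unname(peb_by_tract),
             rank = unname(r),
             percentile = unname((n - r) / n * 100),
             stringsAsFactors = FALSE)
}

#' Estimated reduction in heat-related EMR calls from a canopy change
#'
#' Evaluates a user-supplied canopy-cover -> relative-call-rate lookup at
#' the before and after canopy fractions and returns the percent reduction
#' `(1 - rate_after / rate_before) * 100`. The mapping must cover both
#' canopy levels; no default mapping is claimed as science (the underlying
#' canopy-call regression is external to this package; see
#' [example_canopy_call_mapping()] for a clearly-labelled illustrative
#' lookup).
#'
#' @param canopy_before,canopy_after Canopy fractions, 0-1.
#' @param mapping `data.frame` with columns `canopy` and `rate`
#'   (piecewise-linear lookup).
#' @return Percent reduction in heat-related calls.
#' @export
emr_reduction_estimate <- function(canopy_before, canopy_after, mapping) {
  stopifnot(is.data.frame(mapping), all(c("canopy", "rate") %in% names(mapping)))
  rng <- range(mapping$canopy)
  if (canopy_before < rng[1] || canopy_before > rng[2] ||
      canopy_after < rng[1] || canopy_after > rng[2])
    stop("mapping does not cover the requested canopy range [",
         signif(min(canopy_before, canopy_after), 4), ", ",
         signif(max(canopy_before, canopy_after), 4), "]")
  f <- stats::approxfun(mapping$canopy, mapping$rate)
  (1 - f(canopy_after) / f(canopy_before)) * 100
}

#' Illustrative canopy-to-call-rate mapping
#'
#' A piecewise-linear relative-call-rate lookup constructed to echo
#' published reports that neighbourhoods with sparse canopy receive several
#' times more heat-related ambulance calls. ILLUSTRATIVE ONLY: this is not
#' a fitted epidemiological relationship; substitute a fitted mapping for
#' real analyses.
#'
#' @return `data.frame` with `canopy` and `rate` knots.
#' @export
example_canopy_call_mapping <- function() {
  data.frame(canopy = c(0, 0.022, 0.120, 0.246, 0.40),
             rate = c(1.05, 1.00, 0.60, 0.4653, 0.43))
}

#' Synthetic study-tract land-cover stand-ins
#'
#' Included-class proportions for two synthetic tracts that stand in for
#' the study's dense-core ("downtown") and suburban ("scarborough")
#' census tracts: canopy covers of 2.2% and 3.9% respectively, with the
#' remaining area split between grass and paved surfaces in proportions
#' typical of those urban forms. These are constructed stand-ins, not the
#' real Toronto tract compositions.
#'
#' @return Named list of two proportion vectors over [interest_classes()].
#' @export
study_tract_proportions <- function() {
  list(
    downtown = c(TreeCanopy = 0.022, GrassShrubAgri = 0.080,
                 BareEarth = 0.010, Road = 0.350, OtherPaved = 0.538),
    scarborough = c(TreeCanopy = 0.039, GrassShrubAgri = 0.331,
                    BareEarth = 0.030, Road = 0.250, OtherPaved = 0.350)
  )
}

#' Canopy targets of the bundled cooling designs
#'
#' Proposed canopy covers for the two study-tract stand-ins: 12.0% for the
#' dense core and 24.6% for the suburban tract.
#'
#' @return Named numeric vector of target canopy fractions.
#' @export
study_canopy_targets <- function() {
  c(downtown = 0.120, scarborough = 0.246)
}
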