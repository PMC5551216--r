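test_that("class micro-environments carry the documented surface properties", {
  expect_equal(site_for_class("GrassShrubAgri")$albedo_ground, 0.25)
  expect_true(site_for_class("TreeCanopy")$canopy_overhead)
  expect_equal(site_for_class("TreeCanopy")$svf, 0.2)
  road <- site_for_class("Road")
  expect_equal(c(road$albedo_ground, road$emissivity_ground), c(0.10, 0.90))
  swapped <- site_for_class("Road", cooling_scenario(0.2))
  expect_equal(c(swapped$albedo_ground, swapped$emissivity_ground),
               c(0.30, 0.75))
  expect_error(site_for_class("Water"), "excluded")
})

test_that("canopy addition debits source classes pro-rata and conserves mass", {
  p0 <- study_tract_proportions()$downtown
  same <- apply_design(p0, scenario_spec(canopy_target_fraction = 0.022))
  expect_equal(same, p0, tolerance = 1e-12)

  p1 <- apply_design(p0, cooling_scenario(0.120))
  expect_identical(unname(p1["TreeCanopy"]), 0.120)
  src <- c("GrassShrubAgri", "BareEarth", "Road", "OtherPaved")
  expect_equal(unname(p1[src] / p0[src]),
               rep((1 - 0.120) / (1 - 0.022), 4), tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-12)

  withr::with_seed(21, for (i in 1:50) {
    raw <- runif(5); raw <- raw / sum(raw)
    names(raw) <- c("TreeCanopy", src)
    tgt <- runif(1, raw["TreeCanopy"], raw["TreeCanopy"] +
                   0.9 * (1 - raw["TreeCanopy"]))
    out <- apply_design(raw, scenario_spec(canopy_target_fraction = tgt))
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_equal(unname(out["TreeCanopy"]), tgt, tolerance = 1e-12)
  })

  expect_error(apply_design(p0, scenario_spec(canopy_target_fraction = 0.01)),
               "below current")
  lopsided <- c(TreeCanopy = 0.5, GrassShrubAgri = 0.2, Road = 0.3)
  expect_error(apply_design(lopsided,
                            scenario_spec(canopy_target_fraction = 0.9,
                                          canopy_source_classes =
                                            "GrassShrubAgri")),
               "insufficient")
})

test_that("tract pEB is a convex combination of class budgets", {
  w <- gen_weather(weather_gen_spec(), seed = 31)
  w <- w[w$date %in% unique(w$date)[1:4], ]
  p <- person_params()

  # single-class tract reproduces that class's budget
  grass_only <- tract_peb(c(GrassShrubAgri = 1), w, p)
  site <- site_for_class("GrassShrubAgri")
  eb <- energy_budget(p, w, site)
  manual <- vapply(split(eb, as.Date(w$timestamp, tz = "Etc/GMT+4")),
                   daily_mean_eb, numeric(1))
  expect_equal(grass_only$peb, unname(manual), tolerance = 1e-12)

  # 50/50 mixture is the arithmetic mean of the two class budgets
  half <- tract_peb(c(GrassShrubAgri = 0.5, Road = 0.5), w, p)
  expect_equal(half$peb, (half$eb_GrassShrubAgri + half$eb_Road) / 2,
               tolerance = 1e-12)

  # any mixture stays inside the class-budget envelope
  withr::with_seed(8, for (i in 1:25) {
    raw <- runif(5); raw <- raw / sum(raw)
    names(raw) <- interest_classes <- c("TreeCanopy", "GrassShrubAgri",
                                        "BareEarth", "Road", "OtherPaved")
    mixed <- tract_peb(raw, w, p)
    cls_eb <- as.matrix(mixed[, paste0("eb_", names(raw))])
    expect_true(all(mixed$peb >= apply(cls_eb, 1, min) - 1e-9))
    expect_true(all(mixed$peb <= apply(cls_eb, 1, max) + 1e-9))
  })

  expect_error(tract_peb(c(GrassShrubAgri = 0.7, Road = 0.2), w, p),
               "sum to 1")
})

test_that("the baseline budget is the all-grass full-sky tract", {
  w <- gen_weather(weather_gen_spec(), seed = 32)
  w <- w[w$date %in% unique(w$date)[1:3], ]
  beb <- baseline_eb(w)
  ref <- tract_peb(c(GrassShrubAgri = 1), w)
  expect_equal(beb$beb, ref$peb, tolerance = 1e-15)
})

test_that("added canopy strictly cools a tract under sunny heat-event weather", {
  day <- as.POSIXct("2006-07-30 00:00:00", tz = "Etc/GMT+4") + (0:23) * 3600
  sunny_hot <- weather_record(day, 31, 50, 4.2, "sunny")
  p0 <- study_tract_proportions()$downtown
  p1 <- apply_design(p0, scenario_spec(canopy_target_fraction = 0.25))
  expect_lt(tract_peb(p1, sunny_hot)$peb, tract_peb(p0, sunny_hot)$peb)
})

test_that("design comparison reports paired deltas and handles degeneracy", {
  days <- seq(as.Date("2005-06-27"), by = "day", length.out = 18)
  mk <- function(v) data.frame(date = days, peb = v)
  same <- compare_designs(mk(rep(200, 18)), mk(rep(200, 18)))
  expect_true(same$zero_variance)
  expect_identical(c(same$mean_delta, same$p), c(0, 1))

  shift <- compare_designs(mk(rep(200, 18)), mk(rep(180, 18)))
  expect_identical(c(shift$mean_delta, shift$sd_delta), c(-20, 0))

  withr::with_seed(5, {
    ex <- mk(rnorm(18, 200, 5))
    pr <- mk(ex$peb - rnorm(18, 20, 3))
    cmp <- compare_designs(ex, pr)
    d <- pr$peb - ex$peb
    expect_equal(cmp$t, mean(d) / (sd(d) / sqrt(18)), tolerance = 1e-12)
    expect_equal(cmp$p, 2 * pt(-abs(cmp$t), 17), tolerance = 1e-12)
  })
  expect_error(compare_designs(mk(rep(1, 18)), mk(rep(1, 18))[1:17, ]),
               "same days")
})

test_that("tract ranking is a descending permutation with percentiles", {
  expect_identical(rank_tracts(c(a = 5))$rank, 1L)
  r <- rank_tracts(c(x = 3, y = 2, z = 1))
  expect_identical(r$rank, 1:3)
  expect_identical(r$percentile, c(2, 1, 0) / 3 * 100)

  withr::with_seed(13, {
    v <- rnorm(100); names(v) <- paste0("t", 1:100)
    perm <- sample(100)
    r1 <- rank_tracts(v); r2 <- rank_tracts(v[perm])
    expect_identical(r1$rank[match(r2$tract_id, r1$tract_id)], r2$rank)
    expect_true(all(sort(r1$rank) == 1:100))
    expect_true(all(r1$percentile >= 0 & r1$percentile <= 100))
  })
  ties <- rank_tracts(c(a = 2, b = 2, c = 1))
  expect_identical(ties$rank, c(1L, 1L, 3L))
})

test_that("EMR reduction evaluates the supplied canopy-call lookup", {
  map <- example_canopy_call_mapping()
  expect_identical(emr_reduction_estimate(0.1, 0.1, map), 0)
  expect_equal(emr_reduction_estimate(0.022, 0.120, map), 40,
               tolerance = 1e-9)
  expect_equal(emr_reduction_estimate(0.039, 0.246, map), 50,
               tolerance = 1e-3)
  withr::with_seed(4, for (i in 1:20) {
    a <- runif(1, 0, 0.2); b <- runif(1, a, 0.4)
    expect_gte(emr_reduction_estimate(a, b, map), 0)
  })
  expect_error(emr_reduction_estimate(0.01, 0.9, map), "cover")
})
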