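test_that("the study calendar reproduces the event day counts", {
  cal <- study_calendar()
  expect_identical(as.vector(table(cal$period)[c("Pre", "EHE", "Post")]),
                   c(25L, 18L, 26L))
  expect_identical(nrow(cal), 69L)
  expect_false(anyDuplicated(cal$date) > 0)
})

test_that("weather generation is a pure function of spec and seed", {
  w1 <- gen_weather(weather_gen_spec(), seed = 99)
  w2 <- gen_weather(weather_gen_spec(), seed = 99)
  expect_identical(w1, w2)
  w3 <- gen_weather(weather_gen_spec(), seed = 100)
  expect_false(identical(w1$Ta, w3$Ta))
})

test_that("degenerate spec pins every heat-event hour at the target mean", {
  zero <- weather_gen_spec(ta_sd = c(Pre = 0, EHE = 0, Post = 0),
                           rh_sd = c(Pre = 0, EHE = 0, Post = 0),
                           wind_sd = c(Pre = 0, EHE = 0, Post = 0),
                           diurnal_amp_ta = 0, diurnal_amp_rh = 0)
  w <- gen_weather(zero, seed = 1)
  expect_true(all(w$Ta[w$period == "EHE"] == 29.7))
  expect_true(all(w$RH[w$period == "EHE"] == 53.8))
  expect_true(all(w$wind10[w$period == "Post"] == 5.2))
})

test_that("generated weather respects ranges and window-mean anchoring", {
  w <- gen_weather(weather_gen_spec(), seed = 12)
  expect_true(all(w$RH >= 0 & w$RH <= 100))
  expect_true(all(w$wind10 >= 0))
  expect_true(all(w$sky %in% c("sunny", "partly_cloudy", "cloudy")))

  # moment matching: the daytime-window period means equal the targets
  win <- w[w$hour >= 11 & w$hour <= 18, ]
  day_ta <- aggregate(Ta ~ date + period, data = win, FUN = mean)
  per_ta <- tapply(day_ta$Ta, day_ta$period, mean)
  expect_equal(as.vector(per_ta[c("Pre", "EHE", "Post")]),
               c(23.3, 29.7, 23.3), tolerance = 1e-9)
  per_sd <- tapply(day_ta$Ta, day_ta$period, sd)
  expect_equal(as.vector(per_sd[c("Pre", "EHE", "Post")]),
               c(3.8, 2.5, 3.9), tolerance = 1e-9)
})

test_that("unmatched sampling converges to the targets at large n", {
  cal <- data.frame(event = "one",
                    date = seq(as.Date("2006-07-01"), by = "day",
                               length.out = 2000),
                    period = "EHE")
  spec <- weather_gen_spec(calendar = cal, match_moments = FALSE,
                          stratify_sky = FALSE)
  w <- gen_weather(spec, seed = 77)
  win <- w[w$hour >= 11 & w$hour <= 18, ]
  day_ta <- aggregate(Ta ~ date, data = win, FUN = mean)$Ta
  se <- 2.5 / sqrt(2000)
  expect_lt(abs(mean(day_ta) - 29.7), 3 * se)
})

test_that("the two emulated stations correlate strongly at day level", {
  w <- gen_weather(weather_gen_spec(), seed = 44, average_stations = FALSE)
  expect_setequal(unique(w$station), c("A", "B"))
  day <- aggregate(Ta ~ date + station, data = w, FUN = mean)
  wide <- merge(day[day$station == "A", c("date", "Ta")],
                day[day$station == "B", c("date", "Ta")], by = "date")
  expect_gt(cor(wide$Ta.x, wide$Ta.y), 0.6)
})

test_that("synthetic city compositions are exact integer partitions of tract area", {
  spec <- city_gen_spec(n_tracts = 30, area_range_ha = c(5, 40))
  city <- gen_city(spec, seed = 10)
  expect_identical(city, gen_city(spec, seed = 10))
  counts <- as.matrix(city[, land_classes()])
  expect_equal(rowSums(counts) * 0.36 / 1e4, city$polygon_area_ha,
               tolerance = 1e-12)
  props <- t(apply(counts, 1, proportions_of_interest))
  expect_equal(unname(rowSums(props)), rep(1, 30), tolerance = 1e-12)

  grass_only <- gen_city(city_gen_spec(
    n_tracts = 1,
    alpha = c(TreeCanopy = 0, GrassShrub = 5, BareEarth = 0, Water = 0,
              Building = 0, Road = 0, OtherPaved = 0, Agriculture = 0),
    area_range_ha = c(1, 2)), seed = 2)
  expect_identical(unname(unlist(grass_only[1, land_classes()]) > 0),
                   land_classes() == "GrassShrub")
})

test_that("rendered tract rasters classify back to the generated counts", {
  city <- gen_city(city_gen_spec(n_tracts = 3, area_range_ha = c(0.5, 1)),
                   seed = 6)
  legend <- setNames(seq(20, 230, by = 30), land_classes())
  withr::with_seed(6, for (i in 1:3) {
    counts <- unlist(city[i, land_classes()])
    img <- render_grey_plan(counts, legend, shuffle = TRUE)
    expect_identical(classify_grey_plan(img, legend)[land_classes()],
                     as.numeric(counts), ignore_attr = TRUE)
  })
})

test_that("call generation couples counts to pEB through the log link", {
  expect_error(call_gen_spec(baseline_rate = 0), "> 0")

  peb <- data.frame(tract_id = rep(sprintf("t%03d", 1:100), each = 20),
                    date = rep(seq(as.Date("2005-06-27"), by = "day",
                                   length.out = 20), 100),
                    peb = withr::with_seed(15, rnorm(2000, 180, 25)))
  null <- gen_emr_calls(peb, call_gen_spec(beta = 0), seed = 30)
  expect_lt(abs(cor(null$peb, null$total_calls)), 0.1)
  expect_true(all(null$heat_related_calls <= null$total_calls))

  pos <- gen_emr_calls(peb, call_gen_spec(beta = 0.5), seed = 30)
  r <- correlate(pos$total_calls, pos$peb, "spearman")
  expect_gt(r$estimate, 0)
  expect_lt(r$p, 0.05)

  expect_identical(gen_emr_calls(peb, call_gen_spec(), seed = 8),
                   gen_emr_calls(peb, call_gen_spec(), seed = 8))
})

test_that("weather written to delimited text reads back identically", {
  w <- gen_weather(weather_gen_spec(), seed = 21)[1:200, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather(w, path)
  back <- read_weather(path)
  expect_equal(back$Ta, w$Ta, tolerance = 1e-9)
  expect_equal(back$RH, w$RH, tolerance = 1e-9)
  expect_equal(back$wind10, w$wind10, tolerance = 1e-9)
  expect_identical(back$sky, w$sky)
  expect_identical(back$timestamp, w$timestamp)
})

test_that("heat-alert days are dropped from comparison periods only", {
  x <- data.frame(date = as.Date("2005-06-20") + 0:9,
                  period = rep(c("Pre", "EHE"), each = 5))
  out <- drop_alert_days(x, as.Date(c("2005-06-21", "2005-06-27")))
  expect_identical(nrow(out), 9L)           # one Pre day removed
  expect_true(as.Date("2005-06-27") %in% out$date)  # EHE day retained
})
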