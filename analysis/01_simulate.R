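#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs: hourly two-station weather over the
# four heat-event periods (2005-2010 calendar, 25/18/26 Pre/EHE/Post days)
# and a 544-tract city of land-cover compositions. Everything downstream is
# a deterministic function of these tables and the seed.

suppressPackageStartupMessages(library(heatbudget))
seed <- 1L
dir.create("results", showWarnings = FALSE)

weather <- gen_weather(weather_gen_spec(), seed = seed)
write_weather(weather, "results/weather_hourly.csv")
win <- weather[weather$hour >= 11 & weather$hour <= 18, ]
message(sprintf("weather: %d days, window Ta by period: %s",
                length(unique(weather$date)),
                paste(names(tapply(win$Ta, win$period, mean)),
                      round(tapply(win$Ta, win$period, mean), 1),
                      sep = "=", collapse = ", ")))

city <- gen_city(city_gen_spec(n_tracts = 544), seed = seed + 1L)
write.csv(city, "results/city_landcover.csv", row.names = FALSE)
canopy <- city$TreeCanopy / rowSums(as.matrix(city[, land_classes()]))
message(sprintf("city: 544 tracts, canopy cover %.1f-%.1f%% (median %.1f%%)",
                100 * min(canopy), 100 * max(canopy),
                100 * median(canopy)))
message("wrote results/weather_hourly.csv, results/city_landcover.csv")
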