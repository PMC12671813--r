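#!/usr/bin/env Rscript
# Generate the synthetic study system: a seasonal gridded SST field over
# the northwestern Pacific and one example archival-tag deployment per
# movement strategy (resident released off northern Japan in October;
# migrant released in June, heading south with implanted body-temperature
# events). Writes compact summaries; the full 30-second series are
# regenerated on demand by later scripts (they are deterministic in the
# seed).

library(skipjacktag)
dir.create("results", showWarnings = FALSE)
seed <- 1

field <- simulate_sst_field(
  dates = seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day"),
  seed = seed
)
field_summary <- data.frame(
  month = 1:12,
  sst_36n = sapply(1:12, function(m) {
    d <- field$dates[as.integer(format(field$dates, "%m")) == m]
    mean(sst_lookup(field, d, 36, 141))
  }),
  sst_20n = sapply(1:12, function(m) {
    d <- field$dates[as.integer(format(field$dates, "%m")) == m]
    mean(sst_lookup(field, d, 20, 141))
  })
)
readr::write_csv(field_summary, "results/sst_field_monthly_summary.csv")
message("SST field: Feb@36N ", round(field_summary$sst_36n[2], 1),
        " C, Aug@20N ", round(field_summary$sst_20n[8], 1),
        " C - the resident habitat cools below the 18 C limit in late ",
        "winter while the subtropics stay spawning-suitable (>24 C).")

resident <- simulate_track(c(36.7, 141.4), as.Date("2021-01-05"), 80,
                           "resident", seed = seed)
sim_res <- simulate_sensor_series(resident, field, seed = seed + 1)
migrant <- simulate_track(c(31.59, 144.23), as.Date("2021-06-02"), 80,
                          "migrant", seed = seed)
sim_mig <- simulate_sensor_series(migrant, field,
                                  event_params = list(), seed = seed + 2)

readr::write_csv(resident, "results/example_resident_true_path.csv")
readr::write_csv(migrant, "results/example_migrant_true_path.csv")
readr::write_csv(sim_mig$events, "results/example_migrant_true_events.csv")
message("Example tags: resident wanders near ", round(mean(resident$lat), 1),
        " N; migrant ends at ", round(migrant$lat[nrow(migrant)], 1),
        " N with ", nrow(sim_mig$events), " implanted thermal events.")

daily <- daily_thermal_summary(sim_mig$series)
readr::write_csv(daily, "results/example_migrant_daily_thermal.csv")
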