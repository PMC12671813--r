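# skipjacktag

Analysis toolkit for the southward movement and thermal physiology of
skipjack tuna (*Katsuwonus pelamis*) tagged at the northern limit of
their range off Japan. Two tag types drive the analysis: implanted
archival tags logging depth, peritoneal ("body") temperature, ambient
("water") temperature and light every 30 s, and plastic dart tags
yielding only release/recapture dates and positions. The package
separates two movement strategies — a **spawning-potential group**
moving into warm (>24 °C) water south of 25°N and a **residence group**
wintering near the northern habitat at the 18 °C lethal isotherm — and
characterises their thermal and reproductive biology.

## What it computes

* **Light geolocation + SST-matched smoothing.** Template-fit positions
  (longitude from local noon, latitude from day length via the sunrise
  equation `cos H0 = −tan φ · tan δ`) refined in a daily random-walk
  state-space model: an unscented Kalman filter with a
  Rauch–Tung–Striebel smoother fuses light positions with tag-side SST
  (mean external temperature above 5 m) matched against a gridded SST
  field. Latitude is flagged uninformative within ±3° of solar
  declination around the equinoxes; the SST stream carries it through
  that window. Process noise σ (km/√day) is estimated by maximum
  likelihood. A discrete grid filter provides an independent
  cross-check.
* **Movement metrics.** Haversine daily steps and bearings (6371 km
  sphere), radar summaries, days at liberty, and strict-boundary
  classification at 25°N (track minimum latitude for archival tags,
  recapture latitude for dart tags).
* **Thermal physiology.** Daily mean water / max body temperatures;
  monthly group summaries flagged against the 24 °C spawning and 18 °C
  lethal thresholds; detection of extraordinary body-temperature events
  above 31 °C (= 35 °C red-muscle limit − 4 °C peritoneal gradient) with
  backward onset tracing, inter-event intervals and local-solar onset
  hours; in-package group-average (UPGMA) clustering of daily thermal
  traits.
* **Reproduction.** Gonadal index GI = Gw/FL³ × 10⁴, gonadosomatic index
  GSI = Gw/Bw × 10², and histology-based maturity staging (immature /
  developmental / regression / spawning capable).
* **Mark-recapture summaries.** Southward filtering (released ≥35°N,
  moved ≥0.1° south), decadal recapture rates and pooled
  spawning-potential proportions (equal to recapture-weighted means by
  algebraic identity).
* **Synthetic tag data.** A generator for SST fields, resident/migrant
  tracks, full 30-s sensor series with implanted thermal events, and
  dart-tag cohorts, so the whole chain is testable without any external
  data.

## Worked example

```r
library(skipjacktag)

field <- simulate_sst_field(dates = seq(as.Date("2021-09-01") - 1,
                                        as.Date("2021-09-01") + 101,
                                        by = "day"), seed = 2)
path  <- simulate_track(c(38, 150), as.Date("2021-09-01"), 100,
                        "migrant", seed = 11)
sim   <- simulate_sensor_series(path, field, seed = 12)

raw <- light_geolocate(sim$series, light_threshold = 0.3,
                       sun_alt_deg = light_threshold_alt(0.3))
sst <- tag_sst_daily(sim$series)
trk <- refine_track(raw, sst, field,
                    list(init_latlon = c(38, 150)))
classify_movement_group(trk$lat)
#> movement group: spawning_potential (basis track_minimum_latitude, min lat -4.37)

median(great_circle_km(
  cbind(path$lat, path$lon)[match(trk$date, path$date), ],
  cbind(trk$lat, trk$lon)))
#> [1] 43.17487
```

The fish is classified spawning-potential because its smoothed track
crosses south of 25°N, and the reconstructed positions sit a median of
~43 km from the simulator truth.

The numbered scripts under `analysis/` run the full study: `01` builds
the synthetic data, `02` measures geolocation error and the equinox SST
ablation, `03` reproduces the published mark-recapture table statistics,
`04` recovers implanted thermal events and clusters thermal traits, `05`
stages maturity, and `06` runs the end-to-end pipeline on the resident
and migrant scenarios. Each writes its tables under `results/`.

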