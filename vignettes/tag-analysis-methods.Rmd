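---
title: "Methods: archival-tag movement and thermal physiology analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archival-tag movement and thermal physiology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Skipjack tuna (*Katsuwonus pelamis*) reach the northern limit of their
range in the Kuroshio–Oyashio transition off Japan. Adults leaving that
habitat split into two movement strategies: a **spawning-potential
group** that moves into warm (>24 °C) waters south of 25°N, and a
**residence group** that winters near the northern habitat, drifting
only slowly south as the 18 °C lethal isotherm advances. This package
implements the full analysis chain used to separate and characterise
those strategies from two data sources: implanted archival tags that log
depth, peritoneal ("body") temperature, ambient ("water") temperature
and light every 30 s, and plastic dart tags that yield only
release/recapture dates and positions. Because no raw tag series is
published, a synthetic tag-data generator reproduces the statistical
structure of the system, and every stage is validated against it.

## Light-based geolocation

Daily positions come from the classic template fit. Twilights are found
on the running-median-smoothed log-light curve (window 10 min): dawn is
an upward threshold crossing, dusk the last downward crossing before the
next dawn, so midday attenuation dips shorter than the window (dives) do
not split the day; daylight periods of implausible length (<3 h or
>21 h) are dropped with a warning. Longitude follows from local noon,

\[ \lambda = 15°/\mathrm{h} \times (12\,\mathrm{h} - t_{noon}^{UTC} - EoT), \]

with the equation of time from Spencer's Fourier approximation (max
|declination| ≈ 23.46°, EoT within ±17 min). Latitude solves the sunrise
equation \( \cos H_0 = (\sin\alpha - \sin\phi\sin\delta) /
(\cos\phi\cos\delta) \) where \(H_0\) is the half day arc and \(\alpha\)
the solar altitude the light threshold corresponds to
(`light_threshold_alt()` inverts the logistic sensor model; \(\alpha=0\)
reduces to \( \cos H_0 = -\tan\phi\tan\delta \)). Within ±3° of solar
declination around each equinox (~±8 days) day length carries no usable
latitude information, so the estimate is flagged invalid and its
observation sd inflated to 20°.

## State-space refinement with SST matching

The daily position is a random walk on the sphere with isotropic process
noise σ (km/√day). Three observation streams enter a forward filter /
backward (Rauch–Tung–Striebel) smoother: light longitude (sd 0.5°),
light latitude (sd 1°, or 20° in the equinox window), and tag-side SST —
the mean external temperature above 5 m depth per day — compared with a
gridded SST field at the state position (sd 0.3 °C). The SST observation
is nonlinear in the state, so the measurement update uses the unscented
transform (5 sigma points for the 2-state system, κ = 1). σ is estimated
by maximising the filter log-likelihood with a bounded one-dimensional
search (`stats::optimize`) on [10, 300] km/√day; a divergence guard
re-initialises the covariance after repeated >6σ innovations. A
brute-force discrete smoother over a lat/lon grid
(`grid_filter_oracle()`, separable Gaussian transition kernels,
forward–backward recursion) serves as an assumption-free cross-check; on
the default synthetic scenario the two agree within two grid cells on
more than 90 % of days.

The SST stream matters most in the equinox window. We quantify this with
a controlled ablation: the same raw estimates smoothed with and without
the SST stream, each arm with its own ML process noise. The effect is
isolated on an equinox-spanning *wandering* (resident-style) deployment:
a nearly straight migrant is bridged so well by the motion model alone
that the window contributes little signal, whereas on a wandering track
removing SST roughly doubles the window's median latitude error.

## Movement metrics and classification

Distances are haversine on a 6371-km sphere; bearings are great-circle
initial bearings. Daily steps are computed only for consecutive days
(gaps are not interpolated) and binned into radar sectors centered on
north. Days at liberty is the exclusive date difference
(recapture − release); the published 2021-release rows match this
convention exactly, the 2014/2019/2020 rows are printed one day larger
(inclusive convention) and are reported but not targeted. A fish is
**spawning potential** when its basis latitude is strictly south of
25°N — minimum daily estimated latitude for archival tags (one published
fish is classified spawning-potential despite a 27.4°N recapture),
recapture latitude for dart tags; a fish exactly on the boundary is
residence ("migrated into" the southern area is read strictly).

## Thermal physiology

Daily aggregation is by UTC midnight (positions, hence local time, are
estimates; only onset hours use local solar time, UTC + lon/15). The
extraordinary-event threshold is derived, not assumed: 35 °C red-muscle
overheating limit minus a 4 °C red-muscle-to-peritoneum gradient =
31 °C peritoneal. Events are maximal runs of internal temperature
≥31 °C; runs separated by <10 min merge, runs shorter than 1 min (two
samples) are discarded — both guards exposed in the configuration since
only the 31 °C criterion is prescribed by the physiology. The onset is
traced backward from the threshold crossing along the 5-min-smoothed
series while the temperature is still rising, judged both
sample-to-sample and on a 5-min trend scale (the trend term stops sensor
noise from ending the walk early on shallow ramps), bounded at 120 min,
then refined to the first raw rise. On the simulator's default event
shape (onset→31 °C in 35 min, 5 min rise to the 32 °C peak, 15 min
plateau, 15-min exponential decay) the median onset-timing error is
about 3 min.

Two-group clustering of the daily trait pairs (maximum body temperature,
mean water temperature) uses an in-package agglomerative algorithm with
group-average (UPGMA) linkage on plain Euclidean distances — no scaling,
matching the published choice of axes — with deterministic
lowest-index-pair tie-breaking. The naive O(n³) implementation is
exactly equivalent to `hclust(method = "average")` + `cutree` on
continuous data, which the tests verify on 50 random 200-point sets.

## Reproduction

GI = Gw/FL³ × 10⁴ (g, cm) and GSI = Gw/Bw × 10² (g, g). Histological
staging applies the published criteria in order: postovulatory follicles
or germinal-vesicle-migration/hydrated oocytes → spawning capable;
perinucleolus or cortical-alveolar most-advanced oocytes → immature;
yolked oocytes with atresia ≥50 % → regression; otherwise
developmental. Atresia "absent" is treated as <50 %, mirroring the
published immature rows; the GVM/hydrated rule has no printed row but
follows standard reproductive-phase criteria. Cohort summaries report
sample sd (n−1), undefined for single-sample groups, and flag samples
whose GI falls below the minimum mature GI in the cohort.

## Mark-recapture summaries

The southward filter keeps records released at ≥35°N whose recapture
latitude lies ≥0.1° south of the release. Decades are assigned from the
release date (the only date guaranteed present). The pooled proportion
100·n_sp/(n_sp+n_res) equals the recapture-count-weighted mean of yearly
proportions by the algebraic identity Σwᵢ(xᵢ/wᵢ)/Σwᵢ = Σxᵢ/Σwᵢ, which a
property test verifies on 1000 random partitions to 10⁻¹². The weighted
sd uses the population form; since per-year counts are unpublished, sd
values are reported but not compared.

## The synthetic generator — what it emulates and what it does not

The generator's defaults are the study conditions:

* **SST field** — linear meridional gradient 0.5 °C/deg (colder north),
  seasonal cycle of amplitude 4 °C peaking mid-August, base 24.85 °C at
  30°N, clamped to a 30 °C tropical plateau, plus smooth random
  anomalies (sd 0.1 °C). The base is calibrated so the residence habitat
  (~36–37°N) experiences ~17–18 °C in January–March (at the lethal
  limit) yet exceeds 24 °C in July, and the subtropics stay
  spawning-suitable year-round — the seasonal pattern the monthly
  summaries report.
* **Movement** — residents: truncated-normal daily steps, mean 34.6 km,
  sd 27.6 km, uniform bearings; migrants: mean 77 km, sd 61 km, von
  Mises bearings around due south (κ = 1). Positions advance on the
  6371-km sphere and stay within [−30°, 55°] latitude.
* **Sensors** — external temperature is the field at the interpolated
  position minus 0.05 °C/m of depth, with 0.1 °C noise; internal
  temperature rides a 3 °C thermal excess damped toward 30.5 °C in warm
  water (tuna approach thermoconformity near their upper limit, and the
  published spawning-potential fish showed small body–water differences
  in the tropics); light is a logistic in solar elevation (inflection
  −6°, width 3°) attenuated 0.02/m with 5 % noise; depth is shallow at
  night (~3 m) and deeper by day (~12 m).
* **Events** — onsets at 1–3-day intervals, local solar onset hours
  normal around 16:00 (sd 1.5 h), ramp to the 31 °C threshold in 35 min,
  peak 32 °C, 15 min plateau, exponential decay (τ = 15 min). The ramp
  is anchored so the threshold is reached ~35 min after onset, matching
  the published event narrative.
* **Dart-tag cohorts** — releases uniform in 35–41°N, recaptured with a
  configurable rate, recaptures south of 25°N with a configurable
  probability.

Not emulated: mesoscale oceanography, prey fields, behavioural
thermoregulation dives (available but off by default), fishing-effort
bias in recapture locations, and tag failure. Passing tests therefore
show the pipeline recovers what the generator encodes — movement rates,
seasonal temperatures, event shapes and cohort proportions — not that it
would survive every pathology of real tag data.

## Numerical choices and degenerate inputs

Longitudes live in (−180°, 180°]; all differences are computed modulo
360. Timestamps are UTC throughout; no civil time zones. Sensor noise
defaults (0.1 °C temperature, 5 % light) are implementer choices exposed
in the configuration, as no magnitudes are published. Constant-light
days are skipped with a warning, not an error; a threshold crossing with
|cos H| > 1 flags the latitude invalid rather than raising. The
one-parameter process-noise search trades the full EM treatment for
robustness; the smoother's posterior sd never exceeds the filter's, and
the ML fit is never worse than the search bounds (both tested).
Deterministic runs: every random component flows from an integer seed,
and identical seeds give byte-identical outputs.

Problem sizes in the tests and the acceptance script — a 250-day migrant
deployment, a 12-tag resident cohort, 20 implanted events, 50
clustering replicates of 200 points — are chosen to exercise each
property at the scale of the study system while keeping a full run in
the minutes range.

## Known limitations

The twilight detector and its threshold are a documented replacement for
the proprietary manufacturer software, not a reproduction of it. The
light model's logistic response is an assumption; only threshold
consistency between simulation and template fit is required.
Equinox-window latitude rests entirely on the SST stream, so a biased
SST field would bias those latitudes. The weighted-sd estimator behind
the published ±SD values cannot be checked without per-year recapture
counts. Fishery-effort correction and individual-based modelling are out
of scope.
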