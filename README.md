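# greensurf

Tools for studying **green-wave surfing** by migratory ungulates:
whether animals that start spring migration mistimed with the wave of
plant green-up *compensate en route* — speeding up when behind, slowing
down and using stopovers when ahead — so that they arrive at their
summer range near peak forage quality.

The package is aimed at movement ecologists working with GPS telemetry
and gridded phenology. Because telemetry and satellite archives are
rarely shippable, it includes a seeded synthetic study system (a
corridor landscape plus an agent-based deer simulator) so the entire
workflow is runnable and testable out of the box.

## What it computes

* **Phenology** — per-pixel double-logistic fits to scaled NDVI,
  `NDVI(t) = 1/(1+e^{(x_S−t)/s_S}) − 1/(1+e^{(x_A−t)/s_A})`; the
  Instantaneous Rate of Green-up `IRG(t)` as the spring-component
  derivative (peak `1/(4 s_S)` at `t = x_S`); and the *loss-in-IRG*
  foraging penalty (mean % drop in IRG within ±7 days of the peak).
* **Track processing** — a 10.8 km/h speed filter; migration
  segmentation from net squared displacement via a Richards sigmoid
  `NSD(t) = δ(1+e^{(θ−t)/φ})^{−ν}` with start/end at the 2.5%/97.5%
  crossings; 95% kernel-UD seasonal ranges; movement rate
  (distance/duration).
* **Surfing** — Days-From-Peak (`DFP = fix date − local peak-IRG date`;
  positive = behind the wave) averaged per day and km of each
  migration; start/end mismatches against seasonal-range mean peak
  dates; green-wave propagation segments along the corridor.
* **Stopovers** — Brownian bridge movement model with leave-one-out
  motion-variance estimation, 150-m utilization distributions, a
  variance gate at 8000, and residence days on ≥3-day high-use (10% UD)
  stopovers.
* **Compensation** — early/mid/late timing classes (pooled quartiles of
  annually standardized start dates); full/partial/perfect/non
  compensation classes from start/end mismatch with a 7-day window; a
  proportional-odds model of compensation on absolute start mismatch,
  with `odds_ratio()` giving the per-day odds multiplier.

## Worked example

```r
library(greensurf)

landscape <- make_landscape(landscape_spec(seed = 1))   # 240-km corridor
agent     <- agent_spec(departure_offset = -30, seed = 4) # departs 30 d early
track     <- simulate_deer(landscape, agent)

clean  <- speed_filter(track)                 # 10.8 km/h GPS filter
window <- segment_migration(nsd(clean), track = clean)
window
#> <migration_window> days 95.5-151.3 (55.8 d), 238.0 km straight-line

winter <- seasonal_range(clean, window, landscape, "winter")
summer <- seasonal_range(clean, window, landscape, "summer")
range_mismatch(window, winter)   # -25.9  (started ~26 days ahead of the wave)
range_mismatch(window, summer)   #  -9.3  (arrived ~9 days ahead)
classify_compensation(-25.9, -9.3)
#> [1] full                      # ended closer to peak than it started
movement_rate(window)            # 4.3 km/day
```

The agent left a month before the wave, progressed slowly with stopover
bouts, and let the wave nearly catch up — a *full compensator*. The full
cohort workflow does this for many animals and fits the ordinal model:

```r
report <- run_all(run_config(n_animals = 20, seed = 7))
#> simulate: 240 cells, 20 animal-years
#> segment+surf+stopovers: 20/20 animal-years retained
#> classify: non=2 perfect=4 partial=2 full=12
#> summarize: ordinal beta=0.084 (OR 1.09), wave slope 0.216 d/km
```

`report$records` holds one row per animal-year (mismatches, rate,
stopover days, classes); `report$summary` the per-class means, paired
t/Wilcoxon, ANOVA and z tests; `report$ordinal` the proportional-odds
fit.

## The analysis workflow

The `analysis/` directory runs the same pipeline as six narrative
stages, each writing plain-text tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # landscape + 60-animal cohort
Rscript analysis/02_phenology_fit.R  # NDVI curve fits, penalty profile
Rscript analysis/03_segment.R        # cleaning + NSD migration windows
Rscript analysis/04_surf.R           # DFP profiles, mismatches, wave segments
Rscript analysis/05_stopovers.R      # BBMM motion variance, stopover days
Rscript analysis/06_classify.R       # classes, ordinal model, summaries
```

## Documentation

The methods vignette (`vignettes/green-wave-compensation.Rmd`) explains
the models, the synthetic study system and what it does and does not
emulate, the numerical choices, and known limitations.
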