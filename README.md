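# nyctinast

Analysis tools for group-level nyctinastic plant movement under programmable
light–light–dark schedules.

Some plants (the sensitive plant *Mimosa pudica* is the classic subject)
fold and raise their leaves on a daily rhythm. When a growing area is lit
for two "days" in a row and then left dark for a third, the question is
whether the plants' movement in the hours *before* lights-on anticipates
whether light is coming — and whether that anticipation tracks the number of
light events rather than the passage of clock time. `nyctinast` implements
the full measurement and analysis chain for that kind of experiment:

- **Schedules.** A day of length *N* hours is partitioned `N/4` dark,
  `N/2` light, `N/4` dark; two such lit days (*Light1*, *Light2*) are
  followed by *N* hours of darkness (*Dark*). Phase 1 uses *N* = 24 (72-h
  cycles), Phase 2 uses *N* = 20 (60-h cycles), and Phase 3 redraws *N*
  uniformly from {10, 12, …, 32} h at the start of every cycle. Each day is
  split into *pre-light* `[0, N/4)`, *light-on* `[N/4, 3N/4)` and
  *post-light* `[3N/4, N)` clock intervals (applied to the Dark day too).
- **Motion.** Group-level movement is the mean absolute change of the green
  channel between successive time-lapse frames (one frame per 20 s,
  1920×1080 in the modelled recordings). Frames corrupted by lighting
  transitions (infrared changeover flashes), compressed-video key frames,
  or watering (the event plus the 70 minutes after it) are excluded.
- **Statistics.** Valid frames are averaged into
  (cycle × day-condition × time-of-day) cells. The anticipation statistic
  per cycle is the pre-light motion difference
  `(Light1 + Light2)/2 − Dark`; its growth across cycles is fit as a
  learning curve `d_c = a·log(c) + b`. Designs are summarised with
  repeated-measures ANOVA (cycle as the observational unit, cycle number
  and day length as centred covariates) with partial eta-squared
  `SS_effect / (SS_effect + SS_residual)` per effect.
- **Synthetic data.** A generator produces per-frame motion with known
  condition means, transition spikes, an anticipation effect applied only
  inside a configurable day-length band, and calibrated noise — plus a
  renderer that draws the series as an image sequence — so every stage of
  the pipeline is testable against ground truth without any recordings.

## Worked example

Simulate a Phase-1 experiment (23 three-day cycles of 24-h days) with the
default anticipation curve `0.10·log(c) − 0.18`, then run the analysis:

```r
library(nyctinast)

sched  <- build_phase(1, n_cycles = 23)
longest_dark_run(sched)          # 36  (post-light 6 h + dark day 24 h + pre-light 6 h)

sim    <- simulate_motion(sched, sim_params(seed = 42), capture_interval_s = 300)
series <- apply_exclusions(sim$series, sched)
cells  <- cell_means(series)
diffs  <- motion_difference(cells)
fit    <- fit_log_curve(diffs)
fit
#> Learning-curve fit over 23 cycles:
#>   diff = 0.0954 * log(cycle) + -0.1703   (log base 2.718, r^2 = 0.901)

res <- rm_anova(cells)
res[res$stratum == "unit:condition", ]
#>          stratum          effect sum_sq df  mean_sq f_value  p_value partial_eta_sq
#> 1 unit:condition       condition 0.1787  2 0.089351   283.1 4.20e-25          0.931
#> 2 unit:condition condition:cycle 0.0286  2 0.014276    45.2 3.34e-11          0.683
#> 3 unit:condition        Residual 0.0133 42 0.000316      NA       NA             NA
```

The fitted slope and intercept recover the generator's anticipation curve
to within sampling error; the condition stratum shows the published df
structure (2 effect df against 42 residual df for 23 cycles with the cycle
covariate). Negative early differences — the plants initially moving *more*
before dark days — arise from the negative intercept and flip sign as the
curve grows.

The same analysis runs end to end from a config:

```r
run_pipeline(run_config(1, 23, mode = "synthetic", seed = 42,
                        capture_interval_s = 300, out_dir = "run1"))
```

which writes the schedule, series, cell table, differences, ANOVA tables,
learning-curve fit and a manifest, reproducibly from the seed. A thin CLI
wrapper lives at `inst/cli/nyctinast.R`
(`Rscript nyctinast.R --config run.yaml`).

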