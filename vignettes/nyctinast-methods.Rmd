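---
title: "Methods: schedules, motion quantification and anticipation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: schedules, motion quantification and anticipation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nyctinast)
```

## The experimental model

`nyctinast` analyses group-level nyctinastic movement of plants kept under
a repeating *Light1–Light2–Dark* lighting program. One **cycle** consists
of three "days" of equal length *N* hours: two lit days, each partitioned
dark *N*/4 → light *N*/2 → dark *N*/4, followed by a day of uninterrupted
darkness. Three phases differ only in how *N* is chosen: fixed at 24 h
(Phase 1), fixed at 20 h (Phase 2), or redrawn uniformly from a candidate
set at the start of every cycle (Phase 3, default even hours 10–32; the
set is configurable via `day_lengths` because descriptions of such designs
vary between an 11-level 10–30 h grid and a 10–32 h range).

Each day is also partitioned by clock into three **time-of-day intervals**
— *pre-light* `[0, N/4)`, *light-on* `[N/4, 3N/4)`, *post-light*
`[3N/4, N)` — applied to the Dark day as well, even though its lights never
turn on. The scientifically interesting cell is the pre-light interval: the
plants are in darkness there on every day, so any systematic difference
between lit-day and dark-day pre-light motion reflects anticipation of the
upcoming light state, not a reaction to light itself.

All intervals in the package are half-open `[start, end)`; a timestamp
equal to a boundary belongs to the later segment. This single tie-break
rule makes frame labelling an exact partition (every frame has exactly one
label) and fixes otherwise ambiguous cases such as a frame captured at the
instant of light onset (it is a light-on frame). Time is bookkept in
seconds from the phase origin; no wall clock or timezone enters. A 6 a.m.
onset of a 24-h day corresponds to the local-day offset *N*/4 = 6 h, which
is how all three phases reduce to the one *N*/4–*N*/2–*N*/4 rule. Cycle
indices are 1-based, which matters because the learning curve takes
`log(cycle)`.

## Motion quantification

Motion is the mean absolute difference of the green channel between
consecutive frames (8-bit scale, 0–255). The green channel is the one in
which leaf tissue contrasts most against the background; absolute rather
than signed differences are used because signed pixel change averages to
roughly zero as leaves vacate some pixels and occupy others. The statistic
is symmetric in its two frames and invariant under a common intensity
offset, both of which are tested properties.

Three artifact families contaminate frame differencing in this kind of
recording, and `exclusion_mask()` removes them rather than modelling them:

* **Lighting transitions.** The camera switches between visible and
  infrared mode when the lights change, producing a one-frame global
  flash. The frame spanning each transition is excluded along with one
  frame before and one after (3 frames per transition).
* **Key frames.** Compressed video periodically inserts fully-encoded
  frames whose decoded pixels jump, producing spurious differences at a
  fixed period. The period is an encoding property, not a biology
  property, so the default is *no* key-frame exclusion for directory input
  and a configurable integer period for video-derived series.
* **Watering.** Spraying closes the leaves for an extended time, so the
  event and the 70 minutes after its end are excluded — the window
  `[start, end + 4200 s)`, half-open for consistency with everything else.

A missing or unreadable frame invalidates the two differences it
participates in and the run continues; aborting on a single lost frame
would be wrong for multi-week recordings where occasional capture failures
are a fact of life.

`gaussian_smooth()` (window 50 frames, kernel σ = window/6 so the window
spans about ±3σ) exists for plotting traces only; no statistic uses
smoothed values. Edges and missing values renormalise over the weights
present, so constants pass through unchanged.

## Cell means, the anticipation statistic, and the learning curve

Valid frames are averaged into (cycle × condition × interval) cells. A
cell with no valid frames is flagged missing, never imputed as zero; the
count-weighted cell means reconstruct the global valid-frame mean exactly,
which is the invariant that guards the aggregation.

The per-cycle anticipation statistic is the pre-light **motion
difference** `(Light1 + Light2)/2 − Dark`. It is invariant to adding a
constant to all motion values and antisymmetric under swapping the light
and dark means. Its growth across cycles is modelled as
`d_c = a·log(c) + b`, the form that learning and habituation curves
typically take. The natural log is the default base; the base is
configurable and only rescales the slope (`a_10 = a_e·ln 10`), so no
inference depends on it. With a zero-variance response the slope is zero
and *r*² is reported as `NA` rather than 0 or 1 — `1 − SS_res/SS_tot` is
simply undefined there, and silently reporting either extreme would
mislead.

## Repeated-measures ANOVA

The observational unit is the 3-day cycle. Day condition (3 levels) and
time-of-day (3 levels) are within-unit factors; cycle number and (in
Phase 3) day length enter as centred continuous covariates whose
interactions with each factor are estimated inside that factor's error
stratum. With sum-to-zero contrasts and the balanced within grid the
sequential sums of squares equal the marginal (Type III) ones, so a single
`aov()` multistratum fit suffices.

Two df bookkeeping conventions circulate for such designs: the ANCOVA
view (a stratum for a `df_f`-df factor starts at `(n−1)·df_f` and each
covariate interaction consumes `df_f`) and the summary convention
`df_error = (n−1)·df_factor` with an effective unit count. For 1-df
continuous covariates these coincide exactly — e.g. 23 cycles give
`(23−1)·2 = 44` df in the condition stratum, minus 2 for the
condition×cycle interaction, leaving 42 = `(22−1)·2` — so the package
implements one engine and exposes the count form as `rm_error_df()`. Every
returned row satisfies `MS = SS/df`, `F = MS/MS_res` and
`η²ₚ = SS/(SS+SS_res) ∈ [0,1]` to machine precision; those identities are
what the tests assert, since reproducing recorded *p*-values would require
the original recordings.

`simple_effects()` reruns the same engine on one interval's cells
(condition × cycle only) — the pre-light interval is the usual target. No
multiple-testing correction is applied across simple effects, matching
standard practice for this design. `stratify_by_day_length()` partitions
Phase-3 cycles by whether the drawn day length lies in a band, default
12–24 h with both ends **inclusive**: the band is described as "between 12
and 24 h" in this literature while 12-h and 24-h days are treated as
in-band, so the closed interval is the only consistent reading.

## The synthetic generator

`simulate_motion()` produces per-frame motion with the structure the
analysis assumes: a dark baseline, an elevation while lights are on, an
exponentially decaying spike at every transition, additive Gaussian noise
truncated at zero, and a pre-light anticipation term coded symmetrically —
`+δ(c)/2` on lit days, `−δ(c)/2` on the dark day, with
`δ(c) = a_true·log(c) + b_true` applied only when the cycle's day length
falls inside `anticipation_band`. The symmetric coding is a modelling
choice: the observable statistic constrains only the light–dark
difference, not its decomposition, and symmetry makes the statistic's
expectation exactly `δ(c)`, so estimator bias is directly measurable.
Negative early-cycle differences arise naturally from `b_true < 0`; no
separate mechanism is needed.

Default parameters are chosen to sit on the scale of the published group
descriptives: baseline 0.85 motion units, light boost 0.15, anticipation
(0.10, −0.18), `noise_sd = 0.17`. Package simulations run on a 300-s
capture grid (a 6-h pre-light interval then holds 72 frames), giving
per-cell standard errors of `0.17/√72 ≈ 0.02` — the magnitude of the
published SEMs — while keeping Monte-Carlo suites fast; at that scale the
zero-truncation binds with probability below 10⁻⁶ per frame (5σ), so the
truncation-induced bias is negligible by construction. The transition
spike's e-folding time is `spike_decay_frames` native 20-s frames
(200 s by default) independent of the analysis grid, so coarser grids do
not stretch the spike into neighbouring intervals.

`render_frames()` draws the series as images: leaflets at jittered angles
with tip displacement proportional to the commanded motion, over a
background that steps with the light state — which makes the rendered
sequence reproduce the transition-flash artifact for real.
`inject_artifacts()` adds the flash, key-frame and watering artifacts to a
series; the watering elevation is confined to `[start, end + 70 min)`, the
exact window the exclusion rule removes, so the paired-run oracle (cell
means after injection + exclusion equal the clean run's to 1e-9) is exact
rather than approximate.

What the generator does **not** emulate: pulvinus mechanics, circadian
free-running under constant darkness, touch-triggered (thigmonastic)
responses, slow drifts in leaf coloration, or plant-to-plant
heterogeneity — the model is a group-level signal-plus-noise description.
Passing tests therefore demonstrate that the pipeline measures what it
claims on data with the assumed structure, not that real recordings meet
those assumptions.

## Problem sizes and numerical tolerances

Test and acceptance simulations use 23 cycles × 72 h at the 300-s grid
(~20k frames) for recovery studies, 8 cycles at 900 s for the 200-replicate
null calibration, and 120 rendered frames at 320×180 (the 16:9 shape of
the modelled recordings at desk scale) for the rendering round trip —
sizes chosen so the full suite runs in well under a minute while leaving
Monte-Carlo standard errors small against the effects tested. Exact
analytic checks (schedule arithmetic, noise-free round trips) use
tolerances of 1e-9 to 1e-12; stochastic checks use 3 Monte-Carlo standard
errors or the conventional [0.02, 0.09] band for a nominal 0.05 type-I
rate.

## Known limitations

* Per-plant segmentation and tracking are out of scope; the motion measure
  is group-level by design and cannot attribute effects to individuals.
* The ANOVA engine requires a complete cell table; cycles with missing
  cells must be dropped by the caller (mirroring how days lost to capture
  failures are handled upstream).
* JPEG input requires EBImage; PNG is the native on-disk frame format.
* Recorded-data quantities that depend on the original videos (the
  published descriptive means, fitted coefficients and *p*-values) are
  cross-checked only through arithmetic identities on the published
  summary tables, which ship with the package as plain-text data.
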