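---
title: "Hourly-scale stopover detection for soaring migrants: models, rules and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hourly-scale stopover detection for soaring migrants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why hourly stopovers

Soaring migrants fly on thermal updrafts, and thermals live or die on
the weather of the next few hours. A bird that grounds at 14:00 ahead of
a rain front and leaves at 10:00 the next morning has used a ~20 h
stopover whose start and end carry the weather signal; a daily-scale
rule ("< 100 km moved today") sees at most a vague one-day stop and
destroys the alignment between behaviour and weather. `fptstop` detects
stopovers on the hourly grid, defined behaviourally: any interval of at
least 2 h in which a migrant fails to engage in fast directed flight
during hours when it would otherwise be expected to fly.

## The detection model, stage by stage

**Regularisation.** Tracks are linearly interpolated in lon/lat (after
longitude unwrapping, so the antimeridian is safe) to every top-of-hour
UTC instant. A fix is flagged `interpolated` when no observation lies
within 30 minutes. Gaps longer than `max_gap_h` (24 h default) are never
bridged; the output splits into segments and no downstream operation
crosses a segment boundary. Only migrations with a mean inter-fix
interval under 3 h enter the pipeline at all — with sparser data the
hourly reconstruction is fiction.

**First passage time.** FPT at fix *i* with radius *r* is the time
between the backward and the forward crossing of the circle of radius
*r* centred on *i* (symmetric passage). Crossings are bracketed by
scanning fix-to-fix great-circle distances — because the squared
distance to a fixed centre is convex along a straight segment, a segment
whose endpoints are both inside the circle cannot contain a crossing —
and the crossing instant is then refined by root-finding on the true
great-circle distance along the bracketing segment. We deliberately do
*not* stop at linear interpolation of the distance profile: on oblique
crossings the distance-vs-time curve is visibly concave and linear
interpolation can be off by tens of seconds, which matters because the
test suite holds the implementation to within 1e-3 h of a brute-force
oracle that resamples the trajectory at 1 s resolution. An FPT is
missing when the trajectory never exits the circle on either side before
the data end; missing values are excluded from variances and break
candidate runs.

**Radius selection.** Per migration, the radius in [2500, 6000] m (step
250 m) maximising Var(log FPT) is chosen, ties toward the smaller
radius. This is the scale at which the contrast between transit and
restricted movement is sharpest; the bounds reflect typical hourly
displacement of a soaring migrant (~25–40 km/h cruise) against
stopover-scale confinement. "Variance of log FPT" is implemented as
var(log FPT), the convention of the standard trajectory packages, not
log(var FPT).

**Threshold.** The per-migration cut on log FPT separates "transiting"
from "not transiting". Two functionals are provided:

* `threshold_method = "otsu"` (default): the split maximising the
  between-class variance of the log-FPT values. On migration profiles
  log FPT is strongly multimodal — a flight mode around log(2r/speed),
  an overnight-roost mode near log(15 h), and stopover blocks above —
  and the between-class criterion puts the threshold into the wide empty
  gap above the flight mode, regardless of how much of the migration was
  spent stopped.
* `threshold_method = "mean_sd"`: mean(log FPT) + c·sd(log FPT) with
  `threshold_c = 1` by default.

The default was chosen by the synthetic recovery suite, and this was a
genuine design decision: with realistic overnight roosting, roost fixes
dominate the profile and pull mean + c·sd (any c > 0) above the FPT of
short stopover blocks, so the mean–sd form misses most sub-daily
stopovers (recall ≈ 0.6 on the default synthetic world versus 1.0 for
the between-class split, at equal precision). The mean–sd functional
remains available and fully tested for users who want the classical
form.

A guard `min_log_var` (0.25) disables FPT candidate detection on
profiles with essentially no behavioural heterogeneity (e.g. a pure
constant-speed transit, where any threshold would slice noise); buffer
rescue still runs.

**Candidate runs and endpoint trimming.** Maximal runs of consecutive
fixes with log FPT strictly above the threshold become candidates
`[first fix, last fix]`. FPT at the arrival and departure fixes of a
stationary block is as large as in the middle of the block, so a run
typically includes the departure fix whose *speed* already belongs to
migration; the trim rule removes the first and, independently, the last
fix when its speed strictly exceeds the 95th percentile
(linear-interpolation sample quantile) of speeds inside the interval —
applied once, not iterated. Speeds are forward speeds: `speed[i]` is the
displacement from fix *i* to fix *i+1*.

**The roost-start rule.** "Activity ceased" at the first fix of the
inactive run (speed ≤ 1 km/h) containing the candidate's start. If that
cessation falls in roosting hours (17:00–08:00 local *solar* time — the
longitude offset, not civil zones, because migrations cross zones), the
stopover is deemed to start at 08:00 the following morning (the imminent
08:00 when cessation is pre-dawn), snapped to the next grid fix. If the
adjusted start reaches the interval's end the candidate was an ordinary
overnight roost and is discarded. This rule, not the daylight filter, is
what removes the nightly roost intervals that any threshold below the
roost mode necessarily selects; it also converts "bird roosted, weather
turned bad overnight, bird could not leave until noon" into a stopover
that starts at 08:00 — exactly the behavioural definition. Candidates
whose first fix is itself active (slow-movement stopovers) are left
alone.

**Rejection filters.** After adjustment, intervals shorter than 2 h are
rejected, as are intervals with fewer than 25 % daylight fixes (sun
above the official −0.833° horizon at the fix's position). Rejection
reasons are counted per migration and the stage counts always satisfy
candidates = kept + roost-discards + duration-rejections +
daylight-rejections.

**Buffer rescue.** Fixes not already inside kept intervals are scanned
for maximal contiguous runs in which each successive fix lies within
15 km of the run's running centroid; runs of strictly more than 30 fixes
become stopovers with provenance `buffer`. This catches fly-and-forage
stopovers: slow, tortuous, drifting movement that never produces a high
FPT but stays in one neighbourhood for 30+ hours. Membership against the
running centroid (rather than an all-pairs diameter) is stable and
order-independent for compact clusters and runs in linear time.

**Merging.** Kept and rescued intervals within 1 h of each other merge
(provenance `fpt` dominates); this is plumbing so a single biological
stopover is not fragmented by one sub-threshold fix. Outputs are sorted,
pairwise disjoint, each ≥ 2 h.

## Activity, alignment, models

*Proportion of activity* is the fraction of a stopover's non-roost
(08:00–17:00 local solar) fixes with speed strictly above 1 km/h — the
strict inequality keeps GPS jitter at nominal 1.0 km/h out of "flight".
Note the two daylight notions are deliberately distinct: the rejection
filter uses astronomical daylight, the activity denominator uses the
non-roost window. The most active third (⌈n/3⌉; `floor` available) is
excluded before weather alignment, on the argument that high-activity
stopovers are foraging, not weather avoidance. Ties at the cut exclude
higher total distance first, then earlier start.

*Event alignment.* Each weather variable is differenced hourly
(Δx(t) = x(t) − x(t−1), missing propagates, never across segments) and
windowed at offsets −7…+7 h around the stopover start (and, separately,
end), rounded to the grid. The ±7 h window is wide enough to see a
front arrive and narrow enough not to fold in the previous day's diurnal
cycle. Windows are averaged per individual first and then across
individuals, so an individual with 40 stopovers counts exactly as much
as one with 3; the 95 % band is mean ± 1.96·SE across individuals
(chosen as a normal-approximation CI at the individual level — the unit
of averaging — since the band's definition is otherwise open). A loess
smoother (degree 2, tricube, span 0.5 over the 15 offsets) is applied,
and the *peak lag* is the offset of the extremum with the largest
absolute smoothed change, ties toward 0 then toward negative lags, with
boundary extrema flagged. This operationalises a visual
"peak-rate-of-change" reading so it can be tested.

*Models.* Stopover counts per migration are fit with a Gaussian LMM
(`count ~ population * season + (1 | individual)`), matching standard
practice for this design even though the response is a count (a Poisson
GLMM is available behind a flag but is not the validated default;
factors with a single level are dropped with a warning). Activity is fit
as a binomial GLMM with logit link, successes = active hours,
trials = daytime hours, random intercepts for individuals nested within
population, and unscaled per-stopover mean weather covariates after
greedy correlation pruning: walk the predictors in a configurable
ecological-priority order (thermal updraft velocity first) and keep each
one iff |Pearson r| ≤ 0.6 against everything already kept. Model
selection ("top models") is out of scope by design; the package fits the
specified structures directly.

## The synthetic world

The generator states one world and the tests live in it:

* 20 individuals in 4 populations, spring and fall migrations of
  1100–2600 km at 32 ± 4 km/h cruise with small heading noise; flight
  only outside roosting hours, so ~300 km per clear day.
* Overnight roosting 17:00–08:00 local solar; stationary fixes carry
  30 m GPS jitter (< 0.2 km/h apparent speed).
* Precipitation-front events on 22 % of days, duration log-uniform on
  [2 h, 264 h] — median ≈ 23 h, so about half of all true stopovers are
  sub-daily, matching the duration structure such data show. Onsets are
  mostly mid-afternoon (truncated normal 13:30 ± 2 h over 09–16 local,
  the observed clustering of stopover starts), with 20 % of fronts
  arriving during evening roost (17–23 h), which exercises the
  roost-start rule end to end. Fronts ground the bird completely by
  default (a partial-grounding mode exists to stress the detector).
* Weather: each of ten variables is a diurnal sinusoid in local solar
  time plus AR(1) noise; during fronts precipitation fraction ramps up
  with its largest hourly increment exactly at onset (geometric
  increments), while thermal updraft velocity, shortwave radiation,
  sensible heat flux and boundary height are suppressed, temperature and
  surface pressure dip, total atmospheric water and wind rise, and
  orographic updraft velocity is deliberately uncoupled (the null
  variable).
* Optional foraging bouts: 30–50 h of slow (2–5 km/h) tortuous movement
  within a 5 km radius — the buffer-rescue clientele.
* Ground truth is derived from behaviour, not from the front table: a
  true stopover runs from the first expected-flight hour the bird failed
  to fly until the hour directed flight actually resumed, spanning
  intervening roosts. A front that passes entirely overnight therefore
  produces *no* true stopover, and the detector agrees for the same
  reason (the roost rule collapses the interval).
* Activity outcomes for the GLMM are Bernoulli per daytime hour with
  logit rate β₀ + β·(mean precip, mean thermal, temperature anomaly/10)
  plus nested random intercepts (sd 0.079 each, the published scale).
  The dedicated recovery generator draws stopover-mean covariates on
  matching scales (precipitation Beta with mean 0.25; thermal means
  around 0.3 m/s — low because stopovers oversample suppressed weather;
  temperature as a standardized anomaly), negatively correlating
  precipitation with thermals as weather does.

What the generator does **not** emulate: spatially varying weather along
the route (covariates are a per-migration series), GPS outliers beyond
small jitter, partial flight days from fuel or social constraints,
wind-drift, topography. A green recovery test therefore establishes that
the rule set recovers stopovers whose signature is "not flying when
expected, for hours, coupled to a weather ramp" — not that it would
survive arbitrary real-data pathologies.

## Numerical choices and edge cases

* Crossing refinement tolerance 1e-7 on the unit segment (≲ 0.4 ms);
  oracle agreement is limited by the oracle's own 1 s grid.
* Sample quantile type 7 (R default, linear interpolation) for the trim
  rule; strict inequalities everywhere the rules say "exceeds".
* The 08:00 snap after a roost-start adjustment takes the first grid fix
  at or after 08:00 local solar (ceiling, not nearest), so an adjusted
  start is never earlier than the rule's instant.
* Duplicate timestamps keep the first fix; rows with missing coordinates
  are dropped and counted; a track spanning < 1 h regularises to an
  empty output with a warning; a fully stationary migration has no
  finite FPT anywhere and yields an empty stopover set with a warning.
* Determinism: every stochastic stage consumes an explicit seed; the
  pipeline run twice with one seed produces byte-identical CSVs.

## Known limitations

* The migration table is an input; the net-displacement splitter
  included for convenience is a stand-in, not a validated reconstruction
  of how continuous multi-year tracks should be cut.
* Detected stopover ends sit on the last stationary fix, one hour before
  flight resumes; against resumption-time truth this contributes a
  systematic 1 h end error (the recovery suite's median boundary error).
* The daylight-fraction filter is latitude- and season-sensitive near
  12.5 h daylength; in this package's composition the roost-start rule,
  not that filter, carries the burden of removing roosts.
* Weather covariates are linearly interpolated across sub-24 h gaps like
  positions; whether re-annotation would be preferable is data-dependent
  and out of scope.
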