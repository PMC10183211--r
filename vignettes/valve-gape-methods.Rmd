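---
title: "Methods: valve-gape analysis for combined noise and predator exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valve-gape analysis for combined noise and predator exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapekit)
```

## The measurement problem

Mussels regulate the opening between their shell valves continuously: wide
open while filter feeding, partly or fully closed under disturbance or
perceived predation risk. Valve gape is therefore a convenient behavioural
readout for exposure experiments, logged here by pairs of electromagnetic
coils glued to the two valves -- the field strength at the receiving coil
falls monotonically with coil distance, so the logger record tracks gape.

`gapekit` implements the full chain from raw logger records to inference for
a two-stressor design: playback of boat noise versus an ambient control,
crossed with predator (shore crab) cues at three levels -- no crab, a crab in
a perforated box (chemical cues only), and a free crab sharing the tank. Each
trial runs 75 min: 25 min silence, 25 min ambient playback, then 25 min of
either boat noise or another ambient track; the crab is introduced 5 min
before the sound switch. The logger yields about 47.3 samples per minute
(one per 1.27 s).

## Processing model

**Calibration.** Field-strength readings are mapped to coil distance by
monotone piecewise-linear interpolation of the monitor's calibration pairs
(`calibrate()`). The functional form of the physical calibration is not
prescribed; piecewise-linear interpolation reproduces the calibration knots
exactly, which is the testable contract, and any smooth monotone sensor
curve is approximated to the knot spacing. Readings outside the calibration
hull are an error by default (clamping is opt-in) because extrapolating a
monotone sensor curve is not safe.

**Normalization.** Per individual, the minimum distance over the recording
is subtracted (the closed position at the sensor location) and the result is
divided by its maximum (`normalize_fraction_open()`), giving fraction open
in [0, 1] with both bounds attained. This removes animal size and sensor
placement. Min and max are taken over the full provided trace; a windowed
variant would change the scale of every downstream delta and is deliberately
not the default. The method has a known small-sample property: if an animal
never fully opens or closes during the trial, the observed range understates
the physiological range and all deltas are inflated by the ratio of the two
ranges. This is intrinsic to per-trace min-max normalization, applies
equally to all treatment groups, and is visible in the simulator's parameter
recovery as a small (<15%) upward bias in effect magnitudes.

**Epoch responses.** All windows are half-open `[start, end)` in seconds
from trial start, applied uniformly so boundary samples are never counted
twice. The short-term response is the mean fraction open over the 30 s after
the sound switch minus the 30 s before (`short_term_response()`); the post
window may optionally be shifted past the 10 s crossfade, but by default the
crossfade is included since the exposure begins with it. The long-term
response compares the whole 25 min treatment phase against min 40--44, a
baseline shortly before crab introduction (`long_term_response()`); the
within-individual baseline removes resting-gape differences. Means are
unweighted over samples -- sampling is near-uniform, so time weighting
changes nothing beyond the 4th decimal; a trapezoidal option exists.

**Strong closing events.** Rapid closures are detected on the normalized
trace by a robust threshold rule (`detect_events()`): a centered 15-point
moving average, first differences of that average, and a threshold of
-15 times the standard deviation of the central 50% of the differences.
Numerical choices, all configurable:

* *Alignment*: centered (7 points each side). Event timing is only used for
  window counting, and a centered window places the response symmetrically
  around the closure; trailing alignment is available. A consequence is that
  a detected run starts up to ~half a window before the sample at which the
  drop occurs.
* *Central 50%*: the values between the 25th and 75th percentiles inclusive
  (linear-interpolation quantiles). The alternative reading -- the 50% of
  values nearest the median by rank -- is selectable (`central = "rank"`).
  On Gaussian differences the interquartile-restricted SD converges to
  0.37769 of the full SD (the SD of a normal truncated to its interquartile
  range), which the tests verify by Monte Carlo.
* *Sample SD* uses the n-1 denominator.
* *One threshold per trace*, computed over the whole difference series, not
  per analysis window: the rule describes an individual's own noise floor.
* *Run merging*: an event is a maximal run of consecutive sub-threshold
  differences, reported at the run's first timestamp, so one multi-sample
  closure is one event.
* *Degenerate traces*: if the central differences have zero spread (e.g. a
  constant trace) the threshold is 0, flagged, and no events are reported --
  a threshold of "0" would otherwise count every negative rounding error.

The event-rate change compares events per 10 min between a baseline window
(20.5 min to 1 min before crab introduction) and the treatment phase with a
30 s margin after the switch, so onset-driven closures are excluded.

**Ethogram.** Crab behaviour is a scored transition log over
`away` / `close` / `touching`. `time_budget()` turns a log into occupancy
fractions over a scoring window; the state at the window start must be given
explicitly, the last state persists to the window end, and self-transitions
are collapsed with a warning. Both natural scoring windows -- the last
25 min of the trial and the span from crab introduction -- are supported;
the window is an explicit argument and is recorded in the output, since
published analyses have used both framings.

## Inference

Responses are modelled with GLMs (`fit_glm()`): Gaussian with identity link
for the gape deltas and event-rate change, Poisson with log link for time
spent touching. The Poisson response is constructed as integer seconds of
touching within the scoring window (`touching_seconds()`); the choice of
unit is a genuine open point -- a time expenditure has no canonical count
scale -- so the construction is a documented, configurable default rather
than a claim.

The full model for the gape responses contains the sound treatment, the crab
condition, their interaction, mussel size and crab size. All term subsets
respecting marginality (interaction only with both main effects; 20
candidates for this full set) are fitted and ranked by AICc
(`select_best()`), with

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}.$$

For Gaussian models `k` counts the residual variance as an estimated
parameter (the convention of the common all-subsets selection tools);
`count_dispersion = FALSE` switches to the other convention. Ties are broken
toward fewer parameters, then lexicographically, and recorded. Exact fits
with `n <= k + 1` have undefined AICc and are ranked last (infinite AICc)
rather than dropped.

Reference levels are `ambient` and `no_crab`, so the `treatmentboat`
coefficient is the boat effect. Pairwise crab-condition comparisons use
single-step max-|z| adjusted contrasts (Tukey family, via **multcomp**),
fitted on a model containing the crab factor without the sound-by-crab
interaction -- with an interaction present the level differences are no
longer single contrasts. Only this family is multiplicity-adjusted;
per-condition sound models (`per_condition_sound_models()`) are reported
unadjusted, as separate confirmatory looks at a pattern the selected model
cannot express when the interaction is eliminated. The gape-versus-proximity
model (`gape_vs_proximity()`) regresses the long-term response of
crab-in-tank mussels on the fraction of the scoring window the crab spent
close to or touching them, with the sound treatment in the candidate set and
AICc deciding whether it stays.

## The synthetic-trial generator

No raw data are distributed with studies of this kind, so the package
carries a generator (`simulate_experiment()`) whose output has the
statistical structure the analysis assumes, with known ground truth. The
latent fraction-open path per mussel is

> baseline + OU fluctuation + handling ramp + treatment offsets
> + crab offset + proximity shift + rapid-closure pulses,

clipped to [0, 1] and converted to mm via a per-animal maximum gape
(2.2 mm per cm of shell length, spanning the plausible 7--12 mm range for
3--5.5 cm animals).

* **Ornstein--Uhlenbeck fluctuation** (`ou_theta = 0.005` per s,
  `ou_sigma = 0.08` fraction): slow mean-reverting wander with a ~200 s
  correlation time and closed-form discretization, chosen because real gape
  traces wander smoothly between bouts and the OU process admits exact
  checks. Any smooth stochastic baseline would do; this one is testable.
* **Handling ramp** (`handling_reopen_tau = 300` s): animals start closed
  after sensor attachment and re-open exponentially; 5 min to ~63%
  reopening matches the typical first-phase recovery visible in gape logs.
  `0` disables the ramp for analytic tests.
* **Treatment effects**: a sustained step of `sustained_boat_effect`
  (default -0.08) for the whole boat phase plus a transient extra drop
  `sound_onset_drop` (default -0.03) decaying with `onset_recovery_tau`
  (300 s). The step-plus-transient form makes the long-term effect equal the
  sustained parameter by construction while the short-term metric sees
  onset + sustained.
* **Crab effects**: a sustained `crab_in_tank_effect` (default -0.05) from
  introduction, and a `proximity_effect_slope` (default -0.3) level shift
  active while the simulated crab is close or touching, so the
  time-averaged shift over a window equals slope x time fraction -- the
  quantity the proximity regression estimates. The crab-in-box condition
  carries no effect, matching the finding that chemical cues alone did not
  move the gape.
* **Rapid closures**: Poisson arrivals (`event_rate_baseline = 0.5`,
  `event_rate_boat = 1.5` per 10 min), instantaneous drops of depth
  U(0.2, 0.5) re-opening exponentially (`event_recovery_tau = 60` s) --
  mussels close fast and open gradually. A pulse is only injected when the
  deterministic open level at its onset exceeds the drawn depth: a (nearly)
  closed animal cannot execute a visible rapid closure, and clipping such a
  pulse away would leave phantom ground truth no detector could see. At the
  default baseline this never thins pulses outside the first minutes of the
  handling ramp. `min_event_gap_s` optionally thins
  arrivals to a minimum spacing: closures nearer than the moving-average
  window are intrinsically unresolvable by any difference-based detector, so
  the detector-equals-truth validation uses a 30 s gap while the
  Poisson-mean checks use the pure process (gap 0).
* **Crab behaviour**: a semi-Markov chain over the three states with
  exponential dwell times (means 60/50/10 s) and an embedded transition
  matrix whose long-run occupancy is roughly half away, slightly less close,
  a few percent touching. Only state occupancy matters downstream; the
  dynamics are the simplest process with controllable budgets.
* **Design**: treatments alternate ambient/boat across trials, all three
  crab conditions run within each trial with rotated position assignment,
  the per-trial stimulus crab's size is shared by the trial's three records,
  and per-trial random streams are derived from the master seed by a
  counter so any subset of trials reproduces exactly. 59 trials give the
  study-scale 177 mussel records.

Effect magnitudes are free parameters of the generator: the source design
fixes directions (closing under boat noise, closing with a crab in the tank,
negative gape-proximity correlation), not generative magnitudes. The
defaults above were chosen once to give realistic effect-to-noise ratios at
the study scale and are not tuned thereafter.

**What the generator does not emulate:** sensor drift and temperature
response, non-stationary diurnal/tidal activity rhythms, habituation across
the trial, dependence between the three mussels of a trial (they share a
tank and a playback), crab behavioural responses to sound, and any acoustic
propagation. Passing tests therefore validate the pipeline's bookkeeping and
statistical behaviour under the assumed structure, not the biology of real
traces.

## Validation design and problem sizes

The test suite validates every stage against independent oracles: an
explicit-loop re-implementation of the detector (200 random traces, exact
match), Monte-Carlo checks of the robust threshold's normal-theory constant
(2 x 10^6 draws), Poisson means over 500 seeds, stationary occupancy of the
crab chain against the eigenvector solution, and closed-form GLM fits.
End-to-end experiments run at the study scale: parameter recovery uses 100
replicates of 59 trials with sustained effects -0.10 (boat) and -0.15 (crab
in tank) and all other behavioural effects zero -- including equal closure
rates across phases, since an elevated boat-phase closure rate is itself a
boat effect on the long-term response and would bias the recovered
coefficient. Type-I calibration fits the boat term on 2000 all-null
replicates of 30 trials and expects rejection at 5% +/- 2%. These two runs
dominate the suite's runtime (several minutes each); all other tests run in
seconds.

## Acoustics

Playback construction mirrors the stimulus recipe: short field recordings
are looped into 25 min tracks with 3 s equal-gain linear crossfades
(`loop_with_crossfade()`; the fade-out and fade-in ramps sum to exactly 1,
so constant material is reproduced bit-near-identically), the ambient track
is joined to the treatment track with a 10 s crossfade (`crossfade_join()`),
and tracks are band-passed to 100--1600 Hz (`bandpass()`, zero-phase
forward-backward Butterworth; order 4 per pass gives a maximally flat
passband and >20 dB one octave outside the band).

Characterization uses a Welch averaged periodogram (`psd()`: Hann window,
length 6144, 50% overlap, per-segment mean detrend, one-sided density
normalization -- the overlap and normalization are standard defaults
recorded in the output) and band rms SPL (`band_rms_spl()`):
`20 log10(rms / 1 uPa)` of the 100--600 Hz band-passed pressure, with a
short settling margin trimmed to exclude filter edge transients. SPLs from
several measurement locations aggregate as the arithmetic mean in dB, i.e.
the geometric mean of pressure ratios (`aggregate_spl()`). Calibration is a
uPa-per-file-unit factor applied at WAV read time; WAV interchange is 32-bit
float so calibrated pressures survive round trips.

## Worked example

```{r example, eval = FALSE}
protocol <- trial_protocol()
trials <- simulate_experiment(59, sim_params(), protocol, master_seed = 1)
metrics <- trial_metrics(trials, protocol)
analysis <- analyze_experiment(metrics)
print(analysis)
```

## Known limitations

* Mussels are modelled as independent records; the shared-tank dependence
  within a trial is ignored by design (no mixed effects), matching the
  published analysis but understating standard errors if tank effects exist.
* The normalization-range bias described above affects absolute effect
  sizes, not signs or model selection.
* The Poisson construction for touching time (integer seconds, no exposure
  offset by default) is one of several defensible choices; with a fixed
  25 min scoring window the offset is a constant and only shifts the
  intercept.
* Whether the robust threshold should be computed over the whole trace or
  only the analysis windows is unstated in the source design; the whole
  trace is the default and the windows are configurable.
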