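---
title: "Methods: models, parameters and design choices in optoephys"
author: "optoephys authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`optoephys` quantifies layer-resolved optogenetic electrophysiology and the
accompanying sensory/affective behavior: per-unit stimulus-response metrics
and significance calls for sorted extracellular spike data, population
proportion statistics, von Frey psychometrics and place-preference
readouts, and fiber-optic irradiance estimates. A synthetic-data module
generates sessions with known ground truth so every stage is testable
without recorded data. This vignette documents the models, the parameters
that matter, and the choices made where the design was genuinely open.

# Response windows

All spike metrics are computed in a response window of 1.5 s opening 0.5 s
after stimulus onset; the onset delay discards transients at stimulus
onset and the mechanical actuator's lag relative to its command signal.
Baseline is the 1.5 s before onset. Laser-only trials use the same
windows so the three stimulus conditions (mechanical `M`, laser `L`,
mechanical+laser `ML`) stay comparable.

Windows are half-open: baseline `[-1.5, 0)`, delay gap `[0, 0.5)`,
response `[0.5, 2.0)` relative to onset. This makes window membership a
partition — every spike in the trial span belongs to exactly one window, a
property the test suite checks. A spike exactly at onset therefore counts
in neither baseline nor response.

# Per-unit response metrics

For each unit and condition:

* **Mean rate** `r = (mean spike count per trial) / 1.5 s`, for baseline
  and response windows separately.
* **Modulation index** `MI = (r_stim - r_base) / (r_stim + r_base)`,
  bounded in [-1, 1], undefined (NA) when both rates are zero. MI is
  computed from the window-mean rates, not averaged over per-trial MIs,
  matching the formula as written.
* **Response probability** `RP` = fraction of trials with at least one
  response-window spike.
* **Burst probability** `BP`: spikes preceded by an interspike interval
  (ISI) under 5 ms are part of a burst; consecutive sub-cutoff ISIs merge
  into one burst event; the first spike of a window always opens a new
  event. `BP = bursts / (bursts + single-spike events)`, pooled over
  response windows across trials; ISIs never bridge trials. A unit is
  called bursty when `BP > 0.1` (strict). Only response-window spikes
  enter BP — baseline spiking is excluded.
* **ISI CDFs** are tabulated per unit on a 1 ms grid from within-trial
  response-window ISIs; the population curve is the per-bin median across
  units.

# Unit quality control and classification

* **QC**: accept units with a refractory-period (1 ms) violation fraction
  below 0.5% and an overall rate above 0.1 Hz.
* **Optotagging**: per light pulse, the first-spike latency within a 25 ms
  search window. A unit is tagged when the mean latency is below 9.5 ms
  and the latency SD is below 3 ms (L5 population) or 2 ms (L6-CT), with
  at least half the pulses evoking a response. The search window and the
  responsive-fraction floor are not forced by any published constraint;
  both are exposed in the configuration.
* **Fast-spiking** units (waveform trough-to-peak metric under 215
  microseconds, strict) are excluded from optotagged sets. The metric is
  taken from cluster metadata; computing it from raw waveforms is out of
  scope.
* **Layers**: depths register against a boundary table. The default
  (L2/3 [100, 350), L4 [350, 500), L5 [500, 900), L6 [900, 1300) um) is
  only a configuration default consistent with typical mouse S1 geometry;
  real use requires histology-derived borders per animal.
* **VPL assignment**: the contiguous probe-channel interval spanning the
  first to last channel hosting a unit with significant `M` or `ML`
  modulation; every unit on a channel inside the span is assigned to VPL.

# Modulation inference

A unit is *modulated* in a condition when either test is significant at
`alpha = 0.05`:

1. **Count test**: two-sided Wilcoxon signed-rank on paired per-trial
   baseline vs response spike counts.
2. **Timing test**: a time-locked deviation test. Pooled relative response
   window spike times are compared to temporal uniformity via the maximal
   absolute value of the mean-centered difference between their empirical
   CDF and the uniform CDF. The null distribution comes from circularly
   shifting each trial's spikes by independent uniform offsets (250
   resamples by default); the p-value is the empirical tail probability
   with add-one correction. A Gumbel tail fit to the null maxima is
   available (`method = "gumbel"`) but the assumption-free permutation
   p-value is the default, since the published variants of this test
   differ in their tail approximations.

Direction: *enhanced* / *suppressed* when the count test is significant
with positive / negative mean count change; *timing_only* when only the
timing test fires (these units are tabulated at zero count change);
*none* otherwise. No multiple-testing correction is applied across units
— population tables report per-unit `p <= 0.05` counts, as is standard for
this figure type; a correction flag is available in the configuration.

The analysis span of the timing test equals the count-test response
window, so the two tests see the same data.

## Exact branches and the signed-rank switch point

The signed-rank, rank-sum, McNemar and Friedman tests all carry exact
small-sample branches built from first principles (convolution /
dynamic-programming over the observed, possibly tied, ranks; full
enumeration for Friedman). The signed-rank exact branch is used up to
n = 60 pairs rather than the conventional n = 25: the DP is
O(n * sum(ranks)) and handles midranks, so it is cheap at any realistic
trial count, and on discrete count data the normal approximation is
measurably anticonservative (simulated size about 0.06 at nominal 0.05
with 40 Poisson-count pairs; the exact branch sits at or below nominal).
Keeping the count test at its nominal level keeps the dual-test union
type-I error below 0.10, which the test suite verifies by simulation.

McNemar switches from the exact binomial to the continuity-corrected
chi-square at 25 discordant pairs. The chi-square homogeneity test is
plain Pearson on the k x 2 table (df = k - 1) with an optional Yates
correction for the two-group case; the Marascuillo critical range for
pair (i, j) is `sqrt(chisq_{1-alpha, k-1}) * sqrt(p_i(1-p_i)/n_i +
p_j(1-p_j)/n_j)`, applied to all pairs.

# Behavior

* **von Frey**: eight filaments (0.04–2.0 g) applied five times each in
  ascending order. Once a filament evokes withdrawal on every trial,
  higher filaments are not tested (ascending stop rule); these censored
  filaments are imputed at probability 1.0 and flagged — the stop rule
  only fires after an all-withdrawal filament, so 1.0 is the conservative
  continuation, and the flag lets users exclude them.
* **60% threshold**: the smallest force whose withdrawal probability
  reaches 0.6, interpolated linearly on log10(force) between bracketing
  filaments (the filament series is approximately geometric; no published
  interpolation rule exists, so the geometric axis is the natural choice).
  A curve that never reaches the level returns a censored-above-maximum
  marker.
* **Sensitization AUC**: trapezoidal area of the withdrawal curve over the
  linear force axis (probability x grams), censored points included. The
  axis convention is not standardized; a log10-axis and a normalized
  variant are provided as options and both are reported by the pipeline.
* **Place preference**: `PI = (t_paired - t_unpaired) / (t_paired +
  t_unpaired)`; occupancy comes from uniformly sampled positions against
  chamber rectangles, out-of-arena samples counting as neutral with a
  warning.
* **Paw-lift threshold**: the highest laser intensity whose five trials
  produced no paw lift; used as the per-animal stimulation intensity.
* **Hargreaves** latencies are bookkeeping only: per-trial latencies
  capped at the 20 s cutoff and averaged.

# Fiber optics

Tip irradiance is `P / (pi r^2)`. With the 0.1 mm-core behavioral fiber,
10 mW gives 318.31 mW/mm2; published worked examples computed with
pi ~ 22/7 print 318.18, a discrepancy under 0.05% that the package
documents rather than reproduces. Depth attenuation combines conical
spread with scattering: `T(z) = rho^2 / ((S z + 1)(z + rho)^2)`,
`rho = r sqrt((n/NA)^2 - 1)`, so `T(0) = 1`. Defaults (S = 11.2 per mm,
n = 1.36) follow the widely used brain-tissue irradiance calculator for
blue light in mouse cortex, but published attenuation parameters vary, so
both are configuration values and no depth-irradiance figure is treated
as a reference value.

# The synthetic-data generator

The generator is first-class, tested code. It emulates exactly the
statistical structure the analysis assumes:

* **Baseline rates** lognormal, `meanlog = 0`, `sdlog = 0.85` (median
  1 Hz). Recorded per-unit rate distributions are not published for this
  preparation; a 1 Hz-scale lognormal is the standard heavy-tailed choice
  and both parameters are configuration values.
* **Condition gains** multiplicative on the event rate inside the stimulus
  window after the 0.5 s onset delay: enhancement gain > 1, suppression
  gain < 1 (thinning). No post-stimulus rebound is modelled.
* **Bursts** via a Poisson cluster (Neyman–Scott-like) process: each event
  expands into a burst with per-unit probability (drawn uniformly on
  [0, 0.6] across the population so tonic and bursty regimes coexist),
  with geometrically many extra spikes (mean 2) at 3 ms spacing. This is
  not a biophysical low-threshold-calcium model; the analysis only
  consumes ISI statistics, for which cluster structure suffices.
* **Refractory period**: spikes closer than 1.5 ms to their predecessor
  are suppressed. Without it a pure Poisson train at rate R has an ISI
  under 1 ms with probability `1 - exp(-R/1000)` — at 5 Hz that is 0.005,
  exactly the QC violation cutoff, and half the synthetic population
  fails QC by construction. The QC rule presumes refractoriness, so the
  generator models it; the rate loss is under 1% and negligible against
  every statistical bound used.
* **Optotagged units** emit one spike per 10 ms pulse with reliability
  0.9 at a truncated-normal latency (means 4–8 ms, SDs 0.5–1.5 ms across
  units).
* **Protocol** mirrors the stimulation design: 5 s stimuli, 60 s from `M`
  to `ML` onsets, 30 s otherwise, 40 trials per condition by default,
  preceded by a 40-pulse optotagging block.
* **von Frey** withdrawal is Bernoulli with
  `p = plogis(slope * (log10 f - log10 threshold))`, threshold divided by
  `laser_shift` on laser-on trials, stop rule applied. Default threshold
  0.6 g, slope 8 per decade (steep, as empirical von Frey curves are; at
  this slope the 60% readout lies ~12% above the planted threshold, inside
  the ±25% recovery band used for validation), laser shift 4.
* **Place sessions** are a three-state Markov chain (paired / neutral /
  unpaired) sampled at 1 Hz; chambers are 15x15 cm with an 8x8 cm neutral
  transit zone. Conditioning defaults (stay probabilities 0.95 paired vs
  0.98 unpaired) model aversion to the stimulation-paired chamber;
  baselines use the symmetric mean.

What the generator does **not** emulate: rate adaptation and
non-stationarity, correlated variability across units or trials,
suppression rebound, anesthesia-state dynamics, LFP, waveform shapes
(the fast-spiking metric is planted metadata), or drift in behavioral
state. Passing recovery tests therefore demonstrates that the pipeline
inverts its own generative assumptions, not that those assumptions span
everything real recordings do.

# Determinism and seeds

Every simulator takes an explicit seed and restores the global RNG state
afterwards. Pipelines fan a single configuration seed out to per-stage
derived seeds, so inserting or reordering a stage does not silently
change another stage's draws; reruns with identical configuration and
seed produce byte-identical result tables, which is itself a tested
property.

# Problem sizes used in validation

The shipped verification suite uses: 1000 homogeneous-Poisson units
(40 trials each) for timing-test null calibration; a 200-unit, 40
trial/condition session for direction, burst-probability and
cutoff-robustness recovery; 20 replicate von Frey sessions at 50
trials/filament for threshold recovery; and 100–200 randomized cases per
exact-test enumeration oracle. These sizes give 3-sigma binomial or
Poisson bounds that are decisive for every asserted property while
keeping the whole suite quick on a single core.

# Known limitations

* The timing test evaluates deviation only within the response window; a
  unit locked to the delay-gap transient alone is invisible to it (and to
  the count test), by design of the window convention.
* Exact Friedman enumeration is limited to `(k!)^n <= 2e5` arrangements;
  beyond that the chi-square reference (or the asymptotic branch) applies.
* The censoring imputation (probability 1.0 above an all-withdrawal
  filament) slightly inflates AUC relative to a hypothetical continued
  measurement whenever the true curve would dip — users can exclude
  flagged points.
* Depth-irradiance values inherit the uncertainty of the tissue
  parameters; they are estimates for reporting stimulation strength, not
  dosimetry.
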