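# optoephys

Quantification pipeline for **layer-resolved optogenetic
electrophysiology** and **sensory/affective behavior** in rodent
somatosensory circuits: identify genetically defined cortical populations
in silicon-probe recordings by optotagging, quantify how laser (`L`),
mechanical (`M`) and combined (`ML`) stimulation modulate single-unit
spiking, test those modulations per unit and per population, and score the
behavioral counterparts (mechanical sensitivity, sensitization, place
preference) together with the fiber-optic irradiance actually delivered.

It is written for electrophysiologists and behavioral neuroscientists who
have Phy/Kilosort-curated spike data and trial event tables and want the
full metric-and-statistics chain as reusable, tested functions rather than
one-off scripts. A synthetic-data module generates sessions with known
ground truth, so the entire pipeline is verifiable end to end without any
recorded dataset.

## The quantities at the core

For each unit and condition, spikes are counted in a response window of
1.5 s starting 0.5 s after stimulus onset, against the 1.5 s baseline
before onset:

- mean rate: r̄ = (mean spike count per trial) / 1.5 s
- modulation index: MI = (r̄_stim − r̄_base) / (r̄_stim + r̄_base) ∈ [−1, 1]
- response probability: RP = P(≥ 1 response-window spike per trial)
- burst probability: BP = bursts / (bursts + single-spike events), a
  burst being consecutive spikes with ISIs < 5 ms; bursty iff BP > 0.1

A unit is *modulated* when either a paired Wilcoxon signed-rank test on
trial spike counts or a time-locked deviation (ZETA-style) timing test
with a circular-shift resampling null is significant at α = 0.05.
Population proportions are compared with a Pearson χ² homogeneity test
followed by the Marascuillo procedure, McNemar's exact test for paired
proportions, and Friedman / rank-sum tests — all with exact small-sample
branches. Optotagging uses first-spike latency statistics over light
pulses (mean < 9.5 ms; SD < 3 ms for L5, < 2 ms for L6-CT). Behavioral
readouts: von Frey withdrawal curves under the ascending stop rule, the
60% withdrawal threshold (log-force interpolation), sensitization AUC,
paw-lift intensity thresholds, and the place-preference index
PI = (t_paired − t_unpaired)/(t_paired + t_unpaired). Fiber-tip
irradiance is P/(πr²) with a geometric-spread × scattering model for
depth attenuation.

## Worked example

Simulate a 60-unit session with the default protocol (5 s stimuli, 40
trials per condition, optotagging pulse block), run the full analysis, and
inspect the per-layer population table:

```r
library(optoephys)

cfg <- default_config()
cfg$seed <- 7L
cfg$simulate$n_units <- 60L

res <- run_ephys_pipeline(cfg)
subset(res$proportions, condition == "ML")
#>  group condition  n frac_enhanced frac_suppressed frac_none
#>     L5        ML 26     0.1923077       0.1538462 0.6538462
#>   L2/3        ML 11     0.6363636       0.0000000 0.2727273
#>     L6        ML 18     0.5000000       0.1111111 0.3888889
#>     L4        ML  5     0.6000000       0.0000000 0.4000000
```

Each row gives, per cortical layer, the fraction of units whose `ML`
response was significantly enhanced, suppressed, or unmodulated (the
generator planted a 40/25/35% enhanced/suppressed/flat mixture; layer
splits are small-n). Per-unit metrics sit in `res$metrics`:

```r
head(res$metrics[res$metrics$condition == "ML",
                 c("unit_id", "r_base_hz", "r_stim_hz", "mi", "rp", "bp")], 3)
#>  unit_id r_base_hz r_stim_hz         mi    rp        bp
#>        1 1.1333333 0.8666667 -0.1333333 0.650 0.1282051
#>        2 0.2166667 0.3333333  0.2121212 0.250 0.5000000
#>        3 1.2000000 1.8666667  0.2173913 0.775 0.4259259
```

Unit 3, for instance, fires at 1.2 Hz at baseline and 1.87 Hz during
`ML` (MI = +0.22), responds in 78% of trials, and 43% of its spiking
events are bursts. Irradiance for the powers used behaviorally:

```r
irradiance_table(c(2, 8, 10), depths_mm = c(0.75, 1.0))
#>  power_mW tip_mW_mm2 depth_0.75_mm depth_1_mm
#>         2   63.66198     0.6431562  0.3272218
#>         8  254.64791     2.5726248  1.3088872
#>        10  318.30989     3.2157810  1.6361090
```

10 mW at the 0.1 mm-core fiber tip is 318.3 mW/mm², attenuating to a few
mW/mm² at layer 5–6 depths. The behavior pipeline summarizes simulated
cohorts the same way (`run_behavior_pipeline(cfg)$summary`): with the
default planted hypersensitivity (laser shift 4) the laser-on
sensitization AUC rises from 1.31 ± 0.06 to 1.83 ± 0.01 probability·g,
and conditioning drives the place-preference index to −0.49 ± 0.07
(aversion to the stimulation-paired chamber).

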