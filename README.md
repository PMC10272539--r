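# cardiospinal

Analysis of how spinal cord stimulation (SCS) modulates spinal neuronal
processing of acute myocardial ischemia. Written for cardiac
neurophysiology groups who record (a) multichannel unipolar epicardial
electrograms from a sock array and (b) sorted extracellular spike trains
from a penetrating microelectrode array in the thoracic dorsal horn
(DH) / intermediolateral column (IML) region during a pre- vs post-SCS
coronary occlusion protocol.

## What it computes

**Electrogram markers of sympathoexcitation and arrhythmogenicity.**
Activation time (AT) is the steepest negative slope of the unipolar
electrogram in the QRS; repolarization time (RT) follows the Wyatt
convention (maximum dV/dt of the T wave, either polarity); the
activation recovery interval ARI = (RT − AT), a surrogate of local
action potential duration, shortens under sympathoexcitation. ST
deviation defines the ischemic zone; ARI shortening is the masked mean
of occlusion-minus-baseline ARI; the dispersion of repolarization
DOR = Var(RT) across electrodes (ms²) indexes arrhythmogenic
heterogeneity.

**Firing-rate change (Skellam) test.** Spike counts in a 1-minute
pre-occlusion baseline vs the 3-minute occlusion are compared under the
Poisson-difference framework: K = N₁ − N₂ ~ Skellam(μ₁, μ₂),
P(K = k) = e^−(μ₁+μ₂) (μ₁/μ₂)^(k/2) I₍|k|₎(2√(μ₁μ₂)). The default test
is the exact conditional form (the count split given the total is
Binomial), which stays calibrated for unequal windows; plug-in and
scaled Skellam variants are available. Neurons with a significant rate
increase are **ischemia-sensitive** and are followed across occlusion /
reperfusion pre and post SCS.

**Antidromic IML identification.** Units following more than 60% of
paravertebral stimulation pulses within 50 ms at consistent latency
(SD ≤ 5 ms) are IML; all others are DH. Touch and bradykinin/capsaicin
epochs classify mechanosensitive, nociceptive and multimodal neurons.

**Jitter-normalized synchrony index.** Coincidences (greedy one-to-one
matching, |Δt| ≤ 40 ms) are contrasted with jitter surrogates (target
spikes displaced uniformly within ±200 ms):
SI = (c_obs − null_mean)/(c_obs + null_mean), with one-sided surrogate
rank p-values, evaluated for every DH–DH and DH–IML pair per epoch.

**Synthetic data with ground truth.** Seeded generators produce template
electrograms (exact AT/RT/ST truth by construction) and Poisson spike
populations with ischemia gains, SCS suppression, antidromic units and
injected common drive — the test bed for every stage.

## Worked example

A small synthetic study: 30 neurons (6 ischemia-sensitive with occlusion
gain 3, suppressed to 1.2 post-SCS; 2 antidromic units), 16 electrogram
channels with 0.2 mV ST elevation and 100 ms ARI shortening on the
ischemic quarter.

```r
library(cardiospinal)

tl <- default_study_timeline()
cfg <- study_config(
  synth_spikes = synth_spike_config(
    n_neurons = 30, baseline_rate_hz = 2,
    ischemia_gain = c(rep(3, 6), rep(1, 24)),
    post_scs_gain = c(rep(1.2, 6), rep(1, 24)),
    antidromic = data.frame(neuron = 29:30, latency_ms = 20,
                            latency_jitter_ms = 1, follow_prob = 0.9),
    seed = 42),
  synth_egm = synth_egm_config(n_electrodes = 16, seed = 43),
  egm_timeline = compact_egm_timeline(),
  sync_surrogates = 200, max_sync_neurons = 6, seed = 42)
report <- run_study(cfg)
report
#> <study_report>
#> # A tibble: 7 × 4
#>   stage         n_in  n_out unit
#>   <chr>        <int>  <int> <chr>
#> 1 artifacts   166597 166579 spikes
#> 2 regions         30      2 IML neurons
#> 3 sensitivity     30      7 ischemia-sensitive neurons
#> 4 modalities       7      7 sensitive neurons labelled
#> 5 deltas           7      7 neurons followed
#> 6 egm             16      4 ischemic electrodes
#> 7 synchrony       54      2 significant pairs
```

The stage log is the audit trail: 18 of 166 597 events were removed as
cross-electrode artifacts, both antidromic units were recovered as IML,
and 7 neurons screened ischemia-sensitive (6 true positives plus one
false positive at the α = 0.05 screen).

```r
glance(report)
#> # A tibble: 1 × 6
#>   n_neurons n_sensitive n_iml mean_delta_lad_pre mean_delta_lad_post ...
#> 1        30           7     2               3.42               0.306

report$egm$shortening
#> # A tibble: 2 × 2
#>   phase ari_shortening_ms
#> 1 pre               -101.
#> 2 post              -100.
```

The mean firing response to occlusion drops from +3.42 Hz pre-SCS to
+0.31 Hz post-SCS — the configured suppression, recovered end to end.
ARI shortening is −101 ms against a configured −100 ms (this synthetic
study applied the same shortening pre and post; set
`ari_shortening_ms` differently per phase to emulate an SCS effect on
the myocardium itself).

Single comparisons read naturally too:

```r
skellam_test(118, 60, 1103, 180)
#> Two-window rate-change test (exact)
#>   ref:  118 spikes / 60 s = 1.967 Hz
#>   test: 1103 spikes / 180 s = 6.128 Hz
#>   delta = +4.161 Hz, p = 4.378e-42, direction: increase
```

`tidy()`/`glance()` methods return tibbles for test objects and reports;
`plot_ari_map()`, `plot_rate_series()` and `plot_response_deltas()` give
ggplot views of the main result types. `write_report()` exports every
table as TSV. A thin command-line wrapper is at
`inst/scripts/run_study.R`.

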