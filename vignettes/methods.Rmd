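---
title: "Methods: spinal neuronal and electrogram analysis of myocardial ischemia under spinal cord stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spinal neuronal and electrogram analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

Acute coronary occlusion excites cardiac afferents that project to the
dorsal horn (DH) of the thoracic spinal cord; DH activity drives
preganglionic sympathetic neurons of the intermediolateral column (IML),
whose output raises cardiac sympathetic tone and arrhythmogenic risk.
Spinal cord stimulation (SCS) is thought to dampen this cardio-spinal
loop. `cardiospinal` implements the analysis chain used to quantify that
claim from two data streams recorded in a pre- vs post-SCS occlusion
protocol:

* **multichannel unipolar epicardial electrograms** (a sock array around
  the ventricles), from which activation recovery intervals (ARI, a
  surrogate of local action potential duration), ST-segment deviation,
  the ischemic zone, ARI shortening, and the dispersion of
  repolarization (DOR) are measured; and
* **sorted extracellular spike trains** from a penetrating multielectrode
  array in the DH/IML region, from which ischemia-sensitive neurons,
  antidromically identified IML neurons, stimulus modality classes, and
  pairwise spike synchrony are derived.

All epoch intervals are half-open `[start, end)` seconds so boundary
spikes are counted exactly once. Electrode adjacency is always supplied
as data, never inferred, because probe layouts vary.

## Electrogram metrics

Activation time is the instant of steepest negative slope of the
unipolar electrogram inside the QRS window; repolarization time follows
the Wyatt convention — maximum dV/dt inside the T-wave window regardless
of T polarity, which keeps the estimate consistent for upright and
inverted T waves. Derivatives come from a least-squares local-polynomial
(Savitzky–Golay, order 2) fit; the window is 5 ms for the sharp QRS and
25 ms for the much slower T wave (both configurable, `deriv_window_ms`
and `t_deriv_window_ms`). Ties in the extremal derivative resolve to the
earliest sample, and beats whose peak-to-peak amplitude falls below
`min_amplitude_mv` (default 0.05 mV) are flagged undefined rather than
measured.

ARI is `(RT - AT) * 1000` ms, and the epoch **ARI map** is the
per-electrode mean over valid beats; electrodes with under half their
beats valid are flagged. The per-beat RT estimate at realistic noise has
a few milliseconds of jitter at 1 kHz sampling — the slope of a T wave is
shallow relative to broadband noise — so the epoch mean, not the single
beat, is the estimator of record throughout the package.

ST deviation is the mean amplitude over an ST window minus the mean over
a pre-QRS isoelectric window; depression keeps its negative sign. The
ischemic zone is the set of electrodes whose mean ST deviation during
occlusion strictly exceeds a threshold (default 0.1 mV; the original
adjudication mixes semiautomated software and manual reading and states
no millivolt criterion, so the threshold is exposed). **ARI shortening**
is the masked mean of (occlusion ARI − baseline ARI), negative under
sympathoexcitation. **DOR** is the sample variance (n − 1) across
electrodes of the per-electrode mean repolarization time in ms²; a
configuration switch (`dor_metric = "ari"`) uses ARI variance instead,
since the source work's exact formula is unstated — repolarization-time
variance is the default because DOR is described as heterogeneity of
repolarization time.

## The firing-rate change test

The rate screen compares spike counts in two windows — a 1-minute
pre-occlusion baseline against the 3-minute occlusion — under the
Poisson-difference (Skellam) framework. `dskellam()`/`pskellam()`
implement the Skellam mass and distribution functions exactly
(log-space Bessel evaluation; Poisson-conditioning for the CDF), and
`skellam_test()` offers three variants:

* `"exact"` (default): condition on the total count; under the null the
  test-window count is Binomial with probability
  `dur_test / (dur_ref + dur_test)`. This is the standard exactification
  of the two-window Poisson comparison and is correctly calibrated for
  *unequal* windows.
* `"plugin"`: the raw count difference against
  Skellam(λ̂·d_test, λ̂·d_ref) with the pooled rate plugged in.
* `"scaled"`: both counts rescaled to the shorter window and tested
  against a symmetric Skellam null.

The plug-in variants are noticeably conservative when the windows differ
in length, because the pooled-rate estimate is positively correlated
with the observed difference (the acceptance suite measures the exact
variant's type-I error at ~0.04 and the plug-in variants at roughly half
that or less under the 60 s vs 180 s design). That calibration argument
is why the conditional form is the default; the design intent — "a test
derived from the Skellam distribution" — is preserved, and the variants
are one argument away.

Two-sided p-values double the smaller tail and cap at 1; with zero
spikes in both windows the test is undefined and reports p = 1. A neuron
is **ischemia-sensitive** when the occlusion rate increases significantly
(direction `"increase"` at α = 0.05, per-neuron, no multiplicity
correction by default — the screen's hits are subsequently followed as a
roster, not reported as a family; a Benjamini–Hochberg option exists).
Response deltas are plain rate differences (epoch minus matched
baseline, Hz), negative when firing slows.

## Antidromic IML identification

Paravertebral chain stimulation (60 pulses at 1 Hz in the reference
protocol) activates IML neurons antidromically at near-fixed latency.
For each pulse the first spike in `(pulse, pulse + 50 ms]` is the
candidate response, one-to-one so a spike answers at most one pulse. A
unit is IML when it follows more than 60% of pulses *and* its response
latency is consistent; "consistent delay" is quantified as latency SD
≤ 5 ms (configurable — the source states no number, and antidromic
latencies are near-fixed while chance responses are uniform over the
window, SD ≈ 14 ms).

A sharp limitation is worth stating: with 60 pulses, a unit that
follows pulses at chance probability 0.5 still exceeds the 60% criterion
in `P(Binom(60, 0.5) > 36) ≈ 4.6%` of runs, and nothing in the latency
consistency of true Bernoulli responses removes that floor. The
follow-fraction rule at 60% therefore cannot push false identification
below ~5% at this pulse count; a threshold near 70% would, but 60% is
the stated criterion and is kept.

## Synchrony

Coincidences between a reference and target train are counted by greedy
one-to-one matching in time order: each reference spike takes the
nearest unmatched target spike within the window (|Δt| ≤ 40 ms by
default; the window is read as a ±40 ms proximity criterion, with the
matching rule preventing a burst from inflating the count through a
single partner spike). The chance level comes from jitter surrogates:
each target spike is displaced by an independent uniform draw on
±200 ms — far wider than the coincidence window, far narrower than
epoch-scale rate modulation — and the count is repeated (1000 surrogates
by default; the acceptance checks use 200). The synchrony index is

  SI = (c_obs − null_mean) / (c_obs + null_mean), SI = 0 when both are 0,

so independent high-rate pairs score near zero and locked pairs approach
one; significance is the one-sided surrogate rank
`p = (1 + #{surrogate ≥ c_obs}) / (1 + n_surrogates)`. Pairs with an
empty train in the epoch are flagged undefined and excluded from
aggregates. Population aggregates report, per category (DH–DH, DH–IML)
and epoch, both the count of significant pairs and the summed SI over
significant pairs, because the aggregate's unit in the source figures is
unstated.

## Artifact rejection

On a high-impedance penetrating array one neuron cannot appear on
several electrodes, so sorted events occurring within 0.5 ms on more
than two *adjacent* electrodes are treated as electrical artifacts:
events chain into clusters by ≤ tol gaps, and any connected set of more
than two electrodes in the adjacency graph has its cluster spikes
removed (all involved trains, with a removal log). Pairs and
non-adjacent constellations are always kept; the operation is
idempotent. This is applied to sorted events — the only reading
available downstream of spike sorting, which this package deliberately
treats as upstream.

## The synthetic-data generators

No recordings ship with the package; seeded generators with exact ground
truth stand in for them, and every downstream claim is tested against
that truth.

**Electrograms** are analytic beat templates: the QRS is a
Gaussian-derivative wave whose steepest negative slope falls exactly at
the configured AT, and the T wave is a Gaussian bump positioned so its
steepest positive slope falls exactly at the configured RT (for either
polarity); ST shifts enter with raised-cosine edges placed so their
slopes never compete with the QRS or T wave inside the detection
windows. Defaults: 56 electrodes, 1 kHz, RR 0.6 s (a porcine heart rate
of 100), QRS 1 mV peak with 6 ms width, T wave 0.5 mV with 25 ms width,
AT drawn on 35–50 ms and RT on 320–360 ms (integer ms, so truth lies on
the sample grid), ischemic electrodes +0.2 mV ST and 100 ms RT advance,
noise SD 0.05 mV (5% of QRS). These are template idealizations: real
electrograms have beat-to-beat variability, drift, fractionation and
far-field components the template does not emulate, so recovery tests
certify the detectors' numerics, not their field robustness.

**Spike populations** are piecewise-constant-rate Poisson processes
drawn by thinning, with epoch gains (occlusion gain, post-SCS gain,
arbitrary per-epoch overrides for touch/bradykinin/capsaicin
responses), antidromically driven units (per-pulse Bernoulli follow,
fixed latency ± uniform jitter) superimposed on background firing,
injected common-drive events for synchronized pairs (uniform lag within
±max lag), and a final 1 ms refractory merge. The reference conditions
used by the acceptance checks are 250 neurons at 2 Hz baseline over the
2700 s protocol, 40 ischemia-sensitive neurons with gain 3 pre-SCS and
1.2 post-SCS. Real spinal units burst, adapt and drift; the generator's
Poisson stationarity within epochs is exactly the assumption of the
rate-change test, so end-to-end recovery shows internal consistency, not
robustness to non-Poisson firing.

The default protocol timeline compresses the SCS epoch to 23 min so the
whole record spans 2700 s; no analysis samples the SCS epoch, and the
baseline, occlusion (3 min), reperfusion (3 min) and 1 min post-SCS
baseline match the in-vivo protocol.

## Pipeline and group statistics

`run_study()` chains: artifact rejection → antidromic region labels →
ischemia-sensitivity screen on the pre-SCS occlusion → modality labels
(reported only for the sensitive roster) → response deltas following the
same neurons across occlusion/reperfusion pre and post SCS → electrogram
metrics → pairwise synchrony → group tests. Identity tracking across
epochs is the sorter's: neurons are never re-matched. Each stage logs
counts in/out; any failure aborts with the stage name. Identical
configuration and seed give identical reports.

Group-level comparisons delegate to standard routines: Friedman across
the four delta epochs with Dunn's multiple-comparison z tests
(Bonferroni; implemented in-package as rank-mean z statistics since no
post-hoc package is bundled), Kruskal–Wallis across modality groups
(multimodal takes precedence over single labels), and paired Wilcoxon
signed-rank for synchrony pre vs post. Groups under n = 3 are skipped
with a note. Outlier handling is a median-absolute-deviation *flag*
(never silent removal), replacing the proprietary ROUT procedure used in
the source figures.

By default the pairwise-synchrony stage caps the DH pool at 20 neurons
(190 DH–DH pairs per epoch) to keep surrogate costs linear in what a
desk machine can do; the cap, surrogate count and window are all
configuration fields.

## Numerical and design notes

* Skellam pmf underflow at extreme k is treated as exact zero; the CDF
  sums Poisson tails to 1e-15 mass.
* Beat boundaries round to the nearest sample; detector ties resolve to
  the earliest sample within a 1e-9 relative tolerance band, making all
  detectors deterministic.
* The ischemic-zone threshold is strict (`>`), so a zero threshold
  selects strictly positive ST deviations.
* `identify_iml` requires at least 10 pulses and at least two responses
  before a latency SD (and hence a positive call) is possible.
* Generators restore the caller's RNG state; all seeds are explicit
  arguments.
* Problem sizes in the acceptance checks (2000 test replicates, 56 × 20
  beats, 50 pipeline seeds, 500 synchrony pairs at 200 surrogates, 300
  antidromic seeds) were chosen so each property is measured with a
  standard error well inside its decision band.

## Known limitations

* All calibration statements are under the generator's assumptions
  (stationary Poisson within epochs, template beats); none certify
  behaviour on non-stationary or bursty data.
* The unequal-window rate test is exact only conditionally; the
  marginal plug-in Skellam variants are conservative and remain
  available for comparability.
* The antidromic false-identification floor at 60 pulses (above) is a
  property of the stated criterion, not of the implementation.
* Electrogram beat detection is out of scope: beat marks are inputs (or
  generator truth), as is spike sorting.
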