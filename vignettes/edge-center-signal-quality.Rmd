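---
title: "Comparing signal quality between edge and center sites of planar silicon probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing signal quality between edge and center sites of planar silicon probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Single-shank planar silicon probes carry recording sites both near the
lateral edges of the shank and in its center. Whether site position matters
for signal quality is a practical design question: if edge sites record
larger spikes — for example because the tissue is compressed asymmetrically
around the shank, or because more neurons survive insertion near the edge —
then probes with a limited site count should place their sites at the edge.

`edgesite` implements a complete, testable pipeline for this comparison:

1. **Site grouping** — classify sites of a probe layout as edge or center
   (or group them per column / by longitudinal position) and split a
   multichannel recording into per-group recordings with matched channel
   counts.
2. **Preprocessing** — zero-phase 3rd-order Butterworth band-pass of the
   single-unit band (500–5000 Hz), amplitude subsampling (every 50th sample
   per channel) restricted to ±1000 µV.
3. **Amplitude-distribution analysis** — per-group amplitude PDFs, pooled
   RMS power, a Brown-Forsythe test on signal spread, and a binomial
   cumulative threshold scan that locates the amplitude ranges where one
   group's samples are significantly over-represented.
4. **Noise estimation** — an in vivo noise floor measured in the silent
   down-states of slow-wave activity.
5. **Unit quality** — well-isolation criteria, peak-to-peak amplitudes,
   isolation distance and unit yield for sorted units.
6. **Group statistics** — Mann–Whitney, Kruskal–Wallis and Dunn tests with
   rank effect sizes `r = Z/sqrt(N)`.
7. **Synthetic data** — a ground-truth recording generator so that every
   stage can be validated without access to animal recordings.

## The binomial threshold scan

The central statistic compares cumulative amplitude distributions. Let
`N_e` and `N_c` be the total number of retained (subsampled, range-limited)
amplitude samples from edge and center sites. At an amplitude threshold `x`
on the negative side, count the samples more negative than `x` in each
group: `k_e(x)` and `k_c(x)`. If site position were irrelevant, each of the
`k_e + k_c` samples beyond `x` would be an edge sample with probability

```
p_e = N_e / (N_e + N_c),
```

so `k_e(x)` follows a Binomial(`k_e + k_c`, `p_e`) distribution. A one-sided
exact binomial test (upper tail, evaluated through the regularized
incomplete beta behind `pbinom`, which is stable at pool sizes of 10^7 and
beyond) detects an excess of edge samples; the mirror-image test with
`p_c = N_c/(N_e + N_c)` detects an excess of center samples. The positive
side uses the reverse cumulative counts `P(a > x)` in the same way.

Each side of the amplitude range is divided into 100 uniform thresholds
(10 µV spacing over (0, ±1000]; the end points are chosen so the grid
contains the round −20/−10/+10/+40 µV values that such scans typically
single out). With two tested directions this gives 200 comparisons per
side, and the per-test level is Bonferroni-corrected to
`alpha / 200 = 2.5e-4`. The *selected threshold* is the least extreme
threshold whose edge-direction test is significant — the maximal amplitude
below which edge samples are significantly more abundant (negative side),
or the minimal amplitude above which they are (positive side). The full
significance masks of both directions are returned as well, because the two
directions can each be significant in different parts of one side.

Tie policy: a sample exactly at a threshold is *not* beyond it (`a < x` and
`a > x` are strict), matching the cumulative definitions. Samples exactly
at ±1000 µV are retained; only strictly larger magnitudes are excluded.

The scan is also applied to unit peak-to-peak amplitudes
(`unit_amplitude_scan()`), with thresholds starting at the 60 µV
well-isolation floor.

### What the test assumes

The binomial model treats retained samples as exchangeable between groups.
Subsampling every 50th sample (2.5 ms apart at 20 kHz, longer than a spike)
removes within-spike correlation on one channel, but samples on
neighbouring channels of one group remain correlated through shared
spikes, and all samples beyond a deep threshold may come from a handful of
neurons. The scan therefore detects *any* systematic difference in tail
occupancy — including one caused by where neurons happen to sit relative to
the site groups in a single penetration. Pooled analyses over many
recordings attenuate this; for single synthetic recordings the generator's
balanced population (below) removes it by construction.

## Preprocessing choices

* Zero phase is implemented as forward–backward filtering; the effective
  magnitude response is the squared single-pass response. Edges are handled
  with odd-reflection padding of three times the coefficient length, so
  filtered outputs keep the input length and transients do not leak in.
* The subsample stride starts at the first sample of every channel, and the
  stride is applied per channel, not to the flattened matrix.
* Pooled RMS values are computed on the subsampled pools (the same pools
  the scan uses); `pool_rms()` accepts full-rate vectors when the
  alternative convention is wanted.

## Noise estimation from down-states

Under ketamine/xylazine or urethane anesthesia, cortical firing alternates
between up-states and down-states in which most neurons are silent for a
few hundred milliseconds. Those silent windows approximate the noise floor
of the recording chain in vivo:

1. band-pass (500–5000 Hz) and rectify every channel (MUA),
2. sum channels sample-wise and smooth with a 50 Hz zero-phase low-pass,
3. threshold the envelope at the midpoint of its 10th and 90th percentiles;
   sub-threshold runs of at least 200 ms are down-states, supra-threshold
   runs of at least 100 ms are up-states, shorter runs are merged into the
   surrounding state,
4. in each qualifying down-state, take the centered 50 ms window, compute
   each channel's RMS, average across windows per channel, then across
   channels.

The percentile-midpoint threshold rule and the 100 ms minimum up-state are
this package's choices (a threshold rule must reflect the slow-wave
durations but its exact form is open); both are arguments of
`detect_states()`. The averaging order (windows first, then channels) is
immaterial here because every window spans all channels. RMS is invariant
to rectification, so the estimator can be fed rectified or raw filtered
segments. Validations of this estimator against in vitro measurements show
it reads high by several tens of percent — residual synaptic and distant
spiking activity is present even in down-states — so it should be used
comparatively (edge vs center), not as an absolute noise figure; no
correction is applied.

## Unit quality

A unit is *well isolated* when all three criteria hold, with strict
inequalities as worded: refractory violations below 2 % of spikes
(violations are ISIs under 2 ms; each violating ISI counts one spike), a
firing rate above 0.05 Hz *or* at least 100 spikes, and a peak-to-peak
amplitude above 60 µV. Peak-to-peak is the difference between the trough
and the largest positive peak of the mean waveform on the best channel; a
waveform with no sub-baseline trough uses 0 as the trough and is flagged
atypical.

Isolation distance is the squared Mahalanobis distance — under the
cluster's mean and covariance — of the n-th closest non-cluster spike,
where n is the cluster size; it is undefined when fewer than n other
spikes exist. The feature space is a convention rather than part of the
definition: `waveform_features()` uses the first 3 principal components per
channel of the spike waveforms on the unit's best channel and its
neighbours (12 dimensions for 4 channels), computed over all spikes of the
recording so cluster and non-cluster spikes share one space. A singular
cluster covariance is regularized by diagonal loading of
`1e-6 · trace/d`.

## The synthetic generator

`generate_recording()` produces `[time × channel]` microvolt matrices with
complete ground truth. The model:

* **Slow waves.** Up/down states alternate; durations are gamma-distributed
  with shape 4 and configurable means (defaults 0.5 s up, 0.4 s down).
  Quantitative duration distributions for slow-wave states are not
  standardized; the gamma renewal model is a pragmatic choice giving
  strictly positive, unimodal durations.
* **Spikes.** Each neuron fires as a state-modulated Poisson process
  (defaults: 5–25 Hz in up-states, 0 Hz in down-states — strict down-state
  silence makes the noise estimator's ground truth unambiguous) with an
  enforced 2 ms refractory period. The spike waveform is a biphasic
  template (negative trough, then a smaller positive peak, 1.2 ms support)
  normalized so the configured amplitude is the trough depth — consistent
  with the peak-to-peak definitions downstream.
* **Amplitude decay.** Per site, the spike amplitude is
  `A · exp(−d/λ)` with `d` the Euclidean neuron–site distance and
  `λ = 28 µm` by default; extracellular spike amplitude falls off steeply
  with distance and the exponential is the simplest monotone model with a
  single, configurable scale.
* **Edge asymmetry.** A multiplicative gain on edge-group sites
  (`edge_gain`, 1 = null hypothesis) provides a directly controllable
  effect size for recovery experiments. Modeling the asymmetry as lateral
  tissue compression (displacing neurons) is possible but is not the
  default, because a gain gives an exact, interpretable ground truth.
* **Noise and quantization.** White Gaussian noise per channel (default
  5 µV RMS, within the 2–10 µV range such front ends show), quantized to
  int16 at 0.195 µV/bit (2.34 µV/bit for Neuropixels layouts) and
  de-quantized.

**Balanced population.** The default population is built from base neurons
sampled relative to a column (lateral offset ±25 µm, 8–40 µm off the shank
plane, anchored to a random row present in every column so no replica
falls off a shorter column) and replicated at the same relative
position next to every column. Every column then faces an identical
multiset of neuron distances and amplitudes, so at `edge_gain = 1` the
edge/center comparison is a true null by construction — group differences
can only come from independent spike timing and noise. This is exactly
what a gain-recovery experiment needs; it is *not* how a single real
penetration looks (there, site groups genuinely sample different neurons,
and the scan will report those idiosyncratic differences as significant).
`default_neurons(balanced = FALSE)` provides the unbalanced variant for
robustness checks. Amplitudes (log-normal, median 220 µV at zero distance)
and density (about one neuron per site) were set so the spike-band RMS of
a default simulation is roughly twice its noise floor, the ratio such
cortical recordings show; this is a statement about the generator's
realism, not a fit to any particular dataset.

What the generator does **not** emulate: spatially correlated LFP, probe
drift, electrode impedance noise spectra, the shielding field of the shank,
bursting and cell-type diversity, or spike-sorting errors (units are
consumed with perfect ground-truth labels). Passing recovery tests on this
generator therefore validates the pipeline's statistics and bookkeeping —
not any claim about real tissue.

## Problem sizes in the test suite

The package's validation suite runs entirely on synthetic data: the
effect-recovery experiment uses twenty 60-second, 32-channel recordings per
condition at 20 kHz (edge gain 1.3 vs 1.0, 5 µV noise), the family-wise
error check uses 200 null replicates of 10^5 samples per side, and the
noise-estimator check uses 30-second recordings at 2/4/8 µV noise with
three seeds each. These sizes give the recovery assertions comfortable
statistical margins while keeping a full run of the suite on one CPU core
in the ten-to-twenty-minute range.

## Worked example

```{r, eval = FALSE}
library(edgesite)

lay <- build_layout("neuronexus32")
cfg <- sim_config(lay, duration_s = 60, noise_rms_uV = 5,
                  edge_gain = 1.3, seed = 1)
report <- run_pipeline(cfg)
report
```

The report carries the per-group channel counts, pooled RMS values, the
Brown-Forsythe comparison, both threshold scans with the selected
thresholds and tail percentages, the per-group down-state noise estimates,
and — because ground truth is available — the unit table with yield and the
unit-amplitude scan. `write_report()` serializes it losslessly to JSON.

## Known limitations

* The binomial scan inherits the exchangeability caveat above; on real
  single recordings its significances conflate site-position effects with
  neuron-placement luck.
* The noise estimator requires slow-wave structure; recordings without
  up/down alternation (awake, desynchronized) leave the envelope without
  dynamic range and the segmentation refuses to produce an estimate.
* Spike sorting itself is out of scope: sorted units (or ground-truth
  labels) are consumed, never produced. Reading Phy's binary `.npy` output
  is not supported; a plain-text dialect (`spike_times.csv` +
  per-cluster waveform CSVs) is.
* Internal reference positions of the Neuropixels built-ins are nominal;
  load the true site map from JSON (or pass `reference_sites`) when it is
  known.
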