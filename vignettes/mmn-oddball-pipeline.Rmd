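---
title: "Simulating and analysing oddball ERP experiments: MMN, P3a and cluster-based permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing oddball ERP experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnpipe)
```

## The experiment this package models

In a passive auditory oddball paradigm a frequent *standard* stimulus is
occasionally interrupted by a rare *deviant*. The auditory system's
automatic change detector responds to the deviant with the **mismatch
negativity (MMN)** — a fronto-central negative deflection peaking roughly
100–250 ms after the moment the two stimuli become acoustically
distinguishable — often followed by a fronto-central positivity, the
**P3a**, associated with involuntary attention capture.

`mmnpipe` models the specific variant of this design used to probe lexical
tone perception in Cantonese. The stimuli are the syllables *fu* (lexical
with every tone used here) and *lu* (nonlexical), each carrying tone T1
(high level), T4 (low falling/extra-low) or T6 (low level). Two contrasts
matter: T1/T6, which every native listener discriminates, and T4/T6, the
minimally distinct pair on which some speakers show a *near-merger* —
accurate production with failed perceptual discrimination. Crossing
syllable type × contrast × which member serves as deviant gives eight
blocks of 535 trials (80 deviants, 15%), with 5–11 standards between
consecutive deviants and a 1200 ms onset-to-onset interval (400 ms syllable
+ 800 ms silence). Simulated cohorts come in two groups: *control*
(discriminates everything) and *dissociation* (fails T4/T6 perceptually).

Because the original raw EEG is not publicly deposited, the package ships a
synthetic-EEG generator that stands in for the recordings; everything
downstream of it is the real analysis pipeline and runs unchanged on any
64-channel continuous recording supplied as EDF plus an event table.

## Stimulus model and divergence points

Each syllable is represented by its F0 (pitch) trajectory: a 100 ms
unvoiced onset (F0 = 0) followed by a 300 ms vowel. The contour model is
deliberately schematic — piecewise-linear shapes constrained to reproduce
the two quantities that drive the ERP analysis:

* the **vowel-mean F0** of each condition (fu: 254.9 / 178.6 / 170.9 Hz for
  T1/T4/T6; lu: 284.7 / 180.2 / 184.3 Hz), and
* the **divergence point** of each contrast — the first moment the two
  contours differ. T1/T6 diverges at vowel onset (100 ms post stimulus
  onset); T4 is built to equal T6 sample-for-sample until 200 ms (*fu*) or
  180 ms (*lu*) and to follow a linear segment thereafter.

The post-divergence endpoint of the T4 segment is solved from the
vowel-mean constraint rather than chosen. A consequence worth noting: with
exact pre-divergence identity, the printed means force *fu4* to end
*above* *fu6* (mean difference −7.7 Hz with T6-minus-T4 sign) while *lu4*
falls below *lu6*. The T4 segment is anchored one sample period before the
divergence point so that the first sample at which the contours differ is
exactly the nominal divergence time; the detector
(`divergence_point()`) reports the earliest time from which the absolute
difference stays above tolerance (0 Hz for noise-free synthetic contours).

```{r}
fu4 <- synthesize_contour("fu", "T4")
fu6 <- synthesize_contour("fu", "T6")
divergence_point(fu4, fu6)
mean_f0_difference(fu6, fu4)
```

All ERP latencies downstream are expressed **post-divergence point**, and
every serialized time field is labelled accordingly, because stimulus-onset
and divergence-relative axes coexist throughout this design.

## The synthetic recording

`simulate_block()` produces a vertex-referenced 64-channel recording at
500 Hz from three ingredients:

* **Background noise** — stationary, zero-mean, white by default
  (`noise_spec(sd_uv = 10)`); optional 1/f shaping and a 10 Hz rhythm are
  available. 10 µV per sample is a realistic single-trial amplitude for
  scalp EEG after acquisition filtering.
* **Obligatory components** — N1 (−0.8 µV, 100 ms) and P2 (+0.6 µV,
  200 ms), time-locked to every stimulus onset. They are injected
  identically into standards and deviants so that difference waves cancel
  them; their role is to make the raw averages look like auditory ERPs and
  to verify that the differencing logic removes condition-unspecific
  activity.
* **Deviant components** — MMN and/or P3a per `component_spec()`,
  time-locked to the block's divergence point, injected into deviant trials
  only.

Two modelling choices deserve justification:

**Band-limited component waveforms.** Components are Gaussian pulses in
time (SD 50 ms for MMN, 60 ms for P3a) that are conditioned once on the
1–20 Hz analysis band and renormalised to unit peak before scaling by the
nominal amplitude. A raw Gaussian of this width carries roughly a quarter
of its peak below 1 Hz; any pipeline that high-passes at 1 Hz — as this one
does, following standard MMN practice — would then systematically recover
~25% less than the nominal amplitude, making "inject −1 µV, recover
−1 µV" unattainable *in principle* rather than through noise. Defining the
component inside the band the analysis can see keeps nominal amplitudes
meaningful; the second pass of the analysis filter still costs a few
percent, which is part of what the recovery suite measures.

**Topography and the mastoid reference.** Component topographies are
spherical caps centred on FCz (angular SD 0.9 rad) with small
opposite-sign lobes at the mastoids (−0.15), mimicking the polarity
inversion real MMN generators show below the Sylvian fissure. Weights are
normalised so that the value at the topographic maximum equals the nominal
amplitude *in the mean-mastoid reference*, i.e. after the pipeline's
re-referencing step — the reference in which all measurements are defined.

`simulate_cohort()` adds participant-level variability: a latency shift
drawn from N(0, 25 ms) and a multiplicative amplitude factor from
N(1, 0.1), applied to every deviant component of that participant. The
25 ms figure was chosen to sit in the same order of magnitude as published
between-subject MMN latency SDs (tens of ms). Cohort recordings are
materialised lazily (`realize_recording()`), since 40 participants × 8
blocks of continuous 64-channel data would not fit in memory.

`inject_artifacts()` optionally adds blinks (frontal 150 µV Gaussian
deflections), linear drifts and rectangular extreme excursions at
configurable per-trial rates, to exercise the rejection stage.

## Preprocessing

The chain runs in a fixed order, enforced by a stage flag on the data
objects: **bandpass filter → epoch → extreme-trial scan → ICA hook →
baseline correction → mean-mastoid re-reference → artifact rejection**.

* **Filter**: zero-phase Butterworth, 1–20 Hz, implemented as an order-2
  high-pass cascaded with an order-4 low-pass, each applied
  forward-backward. The half-filters are kept at low orders because the
  transfer-function form of a direct bandpass design is ill-conditioned at
  a 1 Hz edge and 500 Hz rate; the cascade is numerically safe and meets
  the contract (gain within 5% at 10 Hz, over 20 dB down at 50 Hz,
  no group delay). Edges are padded by odd reflection (3 s) before
  filtering.
* **Epochs**: 1800 ms windows, −800…+1000 ms around stimulus onset; time 0
  is the recording sample at the event; events too close to the recording
  edge are skipped and logged.
* **Extreme scan**: trials with any analysis-channel sample beyond ±300 µV
  are removed before the ICA stage, mirroring acquisition practice.
* **ICA hook**: `ica_hook()` is a pass-through slot for an external ICA
  implementation. ICA itself is out of scope and never reimplemented; for
  synthetic data the hook defaults to the identity.
* **Baseline**: the mean of the 800 ms pre-stimulus interval is subtracted
  per channel and trial (exactly zero afterwards, by construction).
* **Re-reference**: every channel becomes x − (M1 + M2)/2; the transformed
  mastoid mean is identically zero.
* **Rejection rules** (any rule on any scalp analysis channel removes the
  trial; mastoids are not scanned): absolute amplitude above 100 µV;
  least-squares linear trend whose |slope| × epoch duration exceeds 75 µV
  (the common operationalisation of a "trend" bound, since the source
  procedure names no formula); *improbable data* — any sample more than 5
  across-trial SDs from the across-trial mean at the same channel and
  latency; *abnormal distributions* — per-epoch kurtosis more than 5 SD
  from the across-trial kurtosis distribution. The kurtosis z-score is
  computed on the log scale: the sampling distribution of kurtosis is
  strongly right-skewed, and a linear 5 SD rule fires on several percent of
  perfectly clean Gaussian trials, which would swamp the artifact signal
  the rule exists to catch. On clean simulated data the full rule set
  removes on the order of 1–2% of trials, comparable to the published
  rejection rates this design reports.

## Difference waves and component measures

Surviving trials are sorted into (i) deviants, (ii) the standard
immediately preceding each deviant, and (iii) the standard preceding each
(ii); a triplet is only formed when all three members survived rejection
(the generator's minimum of two leading standards guarantees every deviant
*can* contribute one). Then

* **true difference wave** = avg(i) − avg(ii),
* **dummy difference wave** = avg(ii) − avg(iii).

The dummy wave is the null reference: it contains exactly the kinds of
noise fluctuation that could masquerade as an MMN, so all inference
compares true against dummy rather than true against zero.

Measurements at FCz (the fronto-central site where these effects are
maximal): **MMN latency** is the most negative sample of the true wave in
the 100–250 ms post-divergence window (earliest sample on ties; a peak on
the window edge is flagged, not discarded). **P3a latency** is the most
positive sample strictly after the individual MMN peak; a wave with no
positive excursion there returns its least-negative sample with a
low-confidence flag so cohort tables stay rectangular. **Mean amplitudes**
average true − dummy over a 100 ms window centred either on grand-average
peak conventions (132 ms for T1/T6 MMN, 136 ms for the *fu* T4/T6 MMN,
202 ms for P3a, all post-divergence) or on per-dataset recomputed centres.
Peaks are plain extrema — no local-maximum requirement — because the
procedure being modelled picks extreme samples.

## Cluster-based permutation test

The test compares true vs dummy waves across participants over the full
channels × time grid while controlling the family-wise error of that
massive comparison:

1. **Pointwise paired t** on (true − dummy), df = n − 1; points with
   |t| above the two-tailed p < .05 critical value are supra-threshold.
   Points with zero across-participant variance get t = 0.
2. **Clustering**: supra-threshold points are joined when they are
   temporal neighbours (±1 sample, same channel) or spatial neighbours
   (neighbouring channels, same sample — no diagonal links), separately
   for positive and negative t. Channel neighbourhoods come from the
   montage: great-circle distance below 0.42 rad on the template sphere, a
   radius chosen once so the median neighbour count is 5 (template-style
   behaviour; configurable). Each cluster's **mass** is its summed t
   (sum-T).
3. **Permutation null**: the paired two-condition exchange — independent
   per-participant sign flips of (true − dummy), 10,000 random partitions
   by default. Each partition contributes its maximum positive and minimum
   negative cluster mass to two null distributions; a cluster is
   significant when its mass falls in the outer 2.5th percentile of the
   matching distribution. Monte-Carlo p-values use the +1-corrected
   estimator, so p ≥ 1/(N+1) and the observed assignment counts as one
   partition. For n participants with 2^n ≤ N an exhaustive mode
   enumerates all sign assignments, which the test suite uses as an oracle.
   Non-significant clusters are reported with their raw p and
   `significant = FALSE` rather than suppressed, so marginal effects stay
   visible.

By default the pipeline clusters the post-stimulus window (0–1000 ms) over
the 62 scalp channels.

`type1_calibration()` ships with the package: it generates datasets with no
deviant-specific effect, runs the reduced test on each, and reports the
family false-alarm rate, which should match the nominal 5% (two 2.5%
tails).

## Orchestration and formats

`run_pipeline()` drives the whole chain from a `default_config()` whose
values are the study's printed parameters; a single master seed fans out
deterministic child seeds per stage, so identical configurations reproduce
byte-identical outputs, and every exported table carries the configuration
hash. Formats: EDF (+ TSV event sidecar) for recordings — written and read
by a minimal EDF implementation (16-bit quantization, one-second records) —
TSV/JSON for sequences, CSV for contours, measures and rejection reports,
JSON for cluster results, YAML for configurations, and a raw-array
container for epochs (little-endian float64 plus a JSON header recording
shape, rate, time axis, labels and stage flags). A thin command-line
front end (`inst/cli/mmnpipe.R`) exposes the `design`, `stimuli`,
`simulate`, `preprocess` and `run` steps for shell use.

## What the validation suite does and does not show

The automated suite (see `tests/testthat/`) validates, at sizes chosen to
keep a full run in tens of minutes on one CPU:

* **Oracle equivalence** — clustering agrees with an independent
  graph-search oracle on 100 random 8 × 50 t-maps, and Monte-Carlo
  p-values agree with exhaustive enumeration at n = 5 within 0.02.
* **Type-I error** — 500 null datasets (n = 12, 200 permutations,
  62 channels × 150 samples) keep the family false-alarm rate in
  [0.02, 0.08] around the nominal 0.05.
* **Parameter recovery** — five independent cohort replicates at the
  study's scale (n = 20, 80 deviants, −1 µV MMN at 132 ms, 25 ms jitter,
  10 µV noise) are pushed through the full pipeline; the across-replicate
  mean grand-average amplitude must land within 0.2 µV of −1 µV, mean
  latency within 10 ms of 132 ms, a significant negative cluster must
  overlap the injected window in at least 95% of replicates, and the
  pooled per-participant latency SD must track the injected jitter within
  30%.
* **Pattern reproduction** — with the default effect table (control: MMN +
  P3a for lexical T1/T6, weak MMN for nonlexical T1/T6 and lexical T4/T6,
  nothing for nonlexical T4/T6; dissociation: MMN for lexical T1/T6 only),
  a reduced cohort (6 per group, 6 µV noise, 199 permutations) reproduces
  the expected presence/absence pattern of significant clusters across the
  eight group × condition cells.
* **Preprocessing contracts** — exact baseline zeroing, exact mastoid-mean
  cancellation, filter gain bounds, and one constructed violation per
  rejection rule.

What passing these suites does **not** show: the generator's noise is
spatially white and stationary, its components are symmetric pulses with a
fixed topography, and participant variability is limited to latency and
amplitude jitter. Real EEG has spatially correlated, non-stationary noise,
overlapping skewed components, per-subject topographies and genuine
artifact structure, and ICA-based cleaning is only hooked, not exercised.
Conclusions about the pipeline's behaviour on real recordings should be
drawn accordingly — the suite certifies the *machinery* (arithmetic,
ordering, inference calibration), not the realism of the generative model.

## Numerical and degenerate-case choices

* Uniform sequence sampling is exact (dynamic programming over constrained
  gap compositions), not heuristic: at the study's parameters the mean of
  79 iid uniform 5–11 gaps (632 standards) far exceeds the 453 available,
  so naive draw-and-reject schemes essentially never terminate and would
  bias the gap distribution if truncated. The leading run is drawn
  uniformly over its feasible range (minimum two standards, so every
  deviant can contribute a full sorting triplet) and the trailing run,
  which the design leaves unconstrained, absorbs the remainder.
* Peak ties resolve to the earliest sample everywhere.
* A channel × sample point with zero across-participant variance
  contributes t = 0 (never NaN/Inf) to the t-map.
* The EDF writer pads the final one-second record with zeros and stores the
  true sample count in the event sidecar, which the reader uses to trim.
* Filtering short signals clamps the reflection pad to the signal length.
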