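---
title: "Models and methods behind sptlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptlearn)
library(dplyr)
```

# The scientific problem

In a serial prediction task (SPT) a participant watches six repetitions of
a short two-element sequence and judges, at the end of each trial, whether
the sequence was disrupted near its end (at stimulus position 10 or 11).
Comparing children with Developmental Coordination Disorder (DCD) with
typically-developing (TD) peers on this paradigm probes the *internal
forward model*: the ability to extract a regularity, predict the next
element, and notice when the prediction fails. Two read-outs matter:

* **Behaviour** — the yes/no discrimination accuracy per sequence type and
  task, and, in the visuomotor variant, the per-stimulus reaction times,
  whose decrease over the first responses indexes sequence learning.
* **Electrophysiology** — the P3, a positive ERP deflection at
  centro-parietal sites (Pz) roughly 400–1000 ms after the disrupting
  stimulus, taken to reflect stimulus evaluation and the updating of a
  mental model. The questions are whether a disrupted-vs-intact difference
  exists at all (cluster test), how large it is (mean amplitude), and
  *when* it happens (percent-area latency) — delayed model updating shows
  up as a latency shift, not necessarily an amplitude change.

`sptlearn` implements this full analysis chain plus a synthetic-data
generator with known ground truth, so that every stage can be validated by
parameter-recovery rather than by eyeballing.

# The synthetic-data generator

`sim_config()` + `simulate_epochs()` / `simulate_behavior()` generate a
cohort with the study's layout: two groups (DCD n = 24, TD n = 23), five
tasks (Control, Spatial, Temporal, Visual, Visuomotor), 60 trials per task
(72 visuomotor), half disrupted at position 10 or 11 (drawn uniformly —
the design uses both positions without a stated ratio), single-channel
epochs at 500 Hz spanning −250..1000 ms around the disruption-locked
stimulus.

**Evoked model.** The P3 is a Gaussian bump: amplitude depends on sequence
type (defaults 3 µV intact, 13 µV disrupted — the *difference* of 10 µV is
what the analyses see), its centre is the participant's true latency plus
single-trial jitter. A Gaussian was chosen deliberately: it is the
simplest shape whose 50%-area latency has a closed form (its centre), so
the latency pipeline can be checked against an exact oracle. Group truth:
mean latency 700 ms (TD) vs 784 ms (DCD) — the non-temporal condition
means of the reported latency table — with a 50 ms between-participant SD
and 40 ms single-trial jitter SD. Neither spread is given in the source
material; 50 ms is a conventional magnitude for between-child P3
variability, and 40 ms is the default adopted for the undocumented
trial-level jitter. Amplitudes carry no group effect, matching the null
amplitude finding.

**Noise model.** Background EEG is synthesized as 1/f ("pink") noise
(spectral shaping of white noise, exponent α = 1, SD 10 µV) plus white
noise (SD 7 µV), i.e. single-trial SD ≈ 12 µV — a plausible magnitude for
band-passed child EEG at Pz. Blinks and saccades are *not* simulated; the
±100 µV rejection stage therefore fires only on rare noise excursions, and
passing tests say nothing about real ocular-artifact contamination.

**Behaviour.** Correctness is Bernoulli per group × task × sequence-type
cell; the default surface averages ≈ .905 (intact) / ≈ .82 (disrupted)
with a group deficit that is absent in the Control task. The correctness
flag is drawn independently of the EEG signal: the analysis links them
only through correct-trial averaging, and the generator makes no stronger
generative claim. Visuomotor RTs follow a decreasing power law,
`RT_k = exp(log(900) + slope · k + ε)`, `ε ~ N(0, 0.2²)`, with group mean
log-slopes −0.098 (DCD) and −0.075 (TD) and a between-participant slope SD
of 0.015, plus 150 ms added at the disrupting stimulus. The slope SD is
the one place where the simulated population is deliberately tighter than
the real one (the reported group test implies an SD nearer 0.03): the
generator's purpose is recovery testing of the *group means* at n =
22/23, and 0.015 represents modest, recoverable individual differences.
Conclusions about real between-child slope heterogeneity should not be
read off these defaults.

All randomness flows from one mandatory seed; participant-level truths are
drawn from a dedicated sub-stream so `simulate_epochs()` and
`simulate_behavior()` agree on the same ground truth
(`ground_truth()`).

# Preprocessing

The chain is fixed: filter → epoch → baseline → reject → exclude →
average.

* `bandpass_filter()` — Hamming-windowed sinc FIR, 0.1–40 Hz, applied with
  group-delay compensation (zero net delay). Transition bands: 1 Hz below
  8 Hz cutoffs but never wider than the cutoff itself (a 1 Hz band around
  0.1 Hz would cross 0 Hz), 25% of the cutoff above 8 Hz; order
  `3.3·fs/min(tb)`. The resulting attenuation is > 20 dB at 0.01 Hz and
  80 Hz (verified in the test suite on probe tones). Simulated epochs are
  generated band-limited, so the pipeline applies the filter only to
  continuous recordings.
* `epoch_trials()` — windows are closed in ms and resolved to the nearest
  sample; the sample at time 0 is included. The temporal task shifts the
  epoch onset by +300 ms (the offset of the shorter stimulus); the
  −250..0 ms baseline is taken relative to the *shifted* zero, since the
  baseline is defined once for all trials.
* `reject_artifacts()` — strict inequality |v| > 100 µV (a sample exactly
  at the threshold is kept);
  a manually supplied blacklist models the manual-inspection half of the
  semi-automated procedure, with no interactive UI. Rejection is pure
  selection: samples are never modified.
* `exclude_low_trial_participants()` — a participant survives a task only
  with ≥ 10 usable trials in *both* sequence types; exclusions are
  reported, never silent.
* `average_erp()` — pointwise mean over retained, correct trials per
  participant × task × sequence type.

# Cluster-based permutation test

`cluster_permutation_test()` operates on per-participant
disrupted − intact difference waveforms at one electrode. Pointwise paired
t-values are thresholded at the two-sided t criterion at
`cluster_alpha = 0.05` (df = n − 1); maximal runs of contiguous
suprathreshold samples of a common sign form clusters, scored by **mass**
(the sum of t), the conventional default for this family of tests (extent
is not used). The null distribution is the maximum |mass| over random
per-participant sign flips; `p = (1 + #{null ≥ obs}) / (1 + n_perm)` (the
+1 correction keeps Monte-Carlo p-values valid), and when `2^n ≤ n_perm`
the full set of sign patterns is enumerated instead, making small-n
results exact and deterministic. Contiguity is temporal only — the
analysis is per-electrode, so no spatial neighbourhood structure exists.
The forming threshold and permutation count are analysis defaults (the
output records them as such); a seed is mandatory for the Monte-Carlo
path. Zero-variance timepoints (possible in noise-free constructed data)
are guarded to a large finite sentinel rather than ±Inf.

`extract_cluster_mean_amplitude()` averages the difference waveform over
the 400–1000 ms P3 window, and `amplitude_anova()` runs the
Condition × Group ANOVA on those difference scores (Type III sums of
squares with sum-to-zero contrasts, since group sizes are unequal after
exclusions; a direct projection fallback handles the zero-residual
degenerate case).

# Percent-area latency and jackknife inference

`fractional_area_latency()` rectifies the difference wave to the positive
polarity (negative samples zeroed — the P3 is a positivity; the source
does not state a rectification rule, and this choice makes the measure
insensitive to small negative excursions), accumulates trapezoidal area
over the measurement window, and linearly interpolates the time at which
50% of the total area is reached. The measurement window is, per
condition, the union span of the significant clusters, falling back to
400–1000 ms when nothing is significant.

Single-subject latencies are too noisy in children, so inference uses
leave-one-out jackknife scoring (`jackknife_latencies()`): N grand
averages, each omitting one participant, each scored for latency. Because
averaging N − 1 of N subjects shrinks between-replicate variance by
(N − 1)², the ANOVA F computed on replicates must be rescaled:

$$F_{adjusted} = F / (N - 1)^2.$$

Here **N is the per-group participant count** — the count of grand
averages built within a group — which is also what makes the adjusted
test's size come out near nominal in the package's own null simulations.
For unequal group sizes the default N generalizes that convention exactly:
`N = 1 + sqrt((n1 + n2 − 2) / (1/(n1−1) + 1/(n2−1)))`, which reduces to
`n` when `n1 = n2` and equals the pooled-variance correction otherwise.
Every result records the N used, and `n_override` switches conventions;
p-values come from F(1, n1 + n2 − 2) on the adjusted statistic.
`mean_group_delay()` then averages the per-condition group differences —
the worked example below.

```{r delay}
published <- read.delim(system.file("extdata", "published_latencies.tsv",
                                    package = "sptlearn"))
mean_group_delay(published,
                 conditions = c("Control", "Motor", "Spatial", "Visual"),
                 groups = c("DCD", "TD"))
```

# Behavioural analyses

* `accuracy_table()` applies the ≥ 10-responses rule and tabulates
  proportion correct per participant × task × sequence type.
* `accuracy_anova()` fits the SequenceType × Condition × Group mixed
  design with `aov()` error strata (participant as the random stratum);
  generalized eta squared uses all error strata in the denominator. With
  a single between factor the Group test is unaffected by the Type-I/III
  distinction even under unequal n.
* `posthoc_group_tests()` uses pooled-variance Student t-tests
  (df = n1 + n2 − 2, matching the conventional reporting) with Cohen's D
  from the pooled SD, flagged at α = .01 to guard the ten comparisons;
  Welch is available by argument.
* `learning_slopes()` takes, per participant, the *median* correct-trial
  RT at each of the first nine stimulus positions (intact and disrupted
  pooled — disruption cannot occur before position 10), fits OLS of
  log RT on position, and compares group slopes with a Welch t-test. The
  median-per-index choice mirrors how such learning curves are summarised
  (mean of median reaction times) and is recorded in the output rather
  than asserted as the only possible reading.
* `disruption_rt_test()` compares the median RT at the disrupting
  stimulus with the same positions of intact trials in a
  SequenceType × Group mixed ANOVA with η²_g, and reports the
  very-first-response Welch t as an overall speed check.

# Numerical choices and degenerate inputs

* Windows are closed in ms, resolved to nearest sample; sub-sample latency
  precision comes from linear interpolation of the cumulative area.
* Zero-area latency inputs raise explicit errors (never NaN); a zero-area
  jackknife replicate aborts the test with a report naming the replicate.
* Zero-variance t statistics (pointwise, post-hoc, or group t-tests on
  constant data) are guarded to a signed finite sentinel (10^6) with a
  warning; zero effect sums of squares yield F = 0 rather than 0/0.
* Identical seeds and configurations give byte-identical outputs; the
  pipeline derives per-stage seeds deterministically from the master seed.

# Problem sizes used in the test suite

The packaged simulations run at the sizes a desk validation of this design
needs: 100 simulations of n = 20 + 20 participants × 60 trials for the
latency-recovery and null-size checks, 500 null simulations × 200
permutations for the cluster-test family-wise error rate, 100 simulations
at n = 22/23 for slope recovery, and exhaustive 64-pattern enumeration
against 2000-draw Monte-Carlo for the permutation oracle. The full
simulated cohort (47 participants, five tasks) is exercised end-to-end by
`run_pipeline()` in `scripts/acceptance.R`.

# Known limitations

* No ICA or ocular-artifact modelling: the generator produces no blinks,
  and the package deliberately has no blink-removal stage (the published
  preprocessing ran ICA in an external toolbox). An EOG-regression hook
  would bolt on before rejection but is out of scope.
* Single electrode only; no spatio-temporal clustering, no topographies.
* The latency estimator inherits a small centre-ward pull from rectified
  background noise and from window truncation (the measured bias on an
  80 ms programmed gap is about −7 ms at the default noise level, within
  the ±10 ms recovery tolerance but not zero). Narrower windows or higher
  SNR shrink it.
* The linear log-RT slope is a two-parameter summary of a power law over
  nine points; it is not a full learning-curve model.
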