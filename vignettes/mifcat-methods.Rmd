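---
title: "Feature-based categorization of vocalizations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based categorization of vocalizations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vocal animals must assign highly variable calls to discrete behavioral
categories: the same call type differs across callers in dominant frequency,
bandwidth, duration and rhythm, while different call types can overlap
completely in their long-term spectra. A classifier therefore needs
selectivity that is simultaneously *fine* (to use spectrotemporal structure
that spectra alone do not carry) and *tolerant* (to generalize over
production variability). `mifcat` implements a feature-based solution:
categories are recognized by detecting a small set of *most informative
features* (MIFs) — rectangular fragments of the cochleagram — and
accumulating the evidence their detections carry.

## The model

**Front-end.** A waveform is converted to a cochleagram: a nonnegative
channels-by-frames map standing in for the firing rates of a population of
auditory nerve fibers. The implementation is a gammatone filterbank
(4th-order, ERB bandwidths, log-spaced center frequencies), half-wave
rectification, power-law compression (exponent 0.3), and per-frame averaging.
Defaults: 64 channels spanning 200 Hz-16 kHz, 1000 frames/s. The front-end is
deliberately pluggable (`make_representation()` plus `frontend_params()`):
the downstream algorithm only requires a nonnegative rate map, so a full
phenomenological auditory-nerve model can be substituted. A `waveform` mode
returns the raw (resampled) signal as a single signed channel, so the
identical template-matching machinery can run on acoustic waveforms as a
control.

**Feature response.** The response of a feature to a call is the maximum over
time lags of the normalized cross-correlation (NCC) between the feature patch
and the same-channel band of the call's cochleagram. At each lag both
template and patch are mean-subtracted and divided by their standard
deviations, so responses lie in $[-1, 1]$ and equal $+1$ for an exact match.
Features are thus detected only within the frequency band they span, but at
any time in the call.

**Threshold, merit, weight.** Responses to 500 within-class and 500
outside-class training calls (at full scale) are binarized at a threshold
$\theta_i$ chosen to maximize the plug-in mutual information
$$I(f_i(\theta_i); C) = \sum_{f_i,C} p(f_i, C)\,
  \log_2 \frac{p(f_i, C)}{p(f_i)\,p(C)}$$
between the detection variable and class membership. The feature's *merit*
is the maximized information in bits; its *weight* is the log-likelihood
ratio $\log_2 [\hat p(f_i{=}1 \mid C{=}1) / \hat p(f_i{=}1 \mid C{=}0)]$.
Weights can be negative: a feature reliably detected only *outside* the
class is informative by its absence.

**Greedy MIF selection.** Starting from the feature of maximal merit,
features are added to maximize *pairwise added information* with respect to
the already-chosen set, until the cumulative total reaches 0.999 bits or the
best candidate adds less than 0.001 bits. This removes the massive
redundancy of the random pool while keeping complementary detectors.

**Classification.** A novel call's evidence is the weight-weighted sum of
MIF detections, normalized by the summed absolute weights of the set. ROC
and DET curves come from sweeping an overall evidence threshold; for
streaming stimuli, detections are binned (50 ms) into per-category evidence
traces.

**Putative MIF neurons.** Each MIF doubles as a template-matching neuron:
its max-NCC response is a membrane-potential proxy $V_m$ converted to a
firing rate by a rectified power law $FR = k\,\lfloor V_m - \theta
\rfloor^{p}$ with $p = 4$ and arbitrary scale $k$. Tuning curves over a
parametric stimulus battery (tones, linear FM sweeps and sweep trains, AM
tones, noise, clicks, two-tone combinations), natural-versus-reversed call
preferences, and stimulus reconstructions from detection times follow from
this correspondence.

## Conventions and numerical choices

* **Dual priors.** Threshold search uses class prior $p(C) = 0.10$ (the
  within-class base rate of the search convention); merit and added
  information are *reported* at the balanced prior 0.5, under which 1 bit
  corresponds to perfect binary classification. Both are configurable in
  `task_spec()`. This reconciles a low-prior search with the "1 bit =
  perfect" reporting scale: $H(C)|_{p=0.1} \approx 0.47$ bits would
  otherwise cap reported merits.
* **Threshold grid.** Candidate thresholds are the midpoints between
  consecutive sorted unique pooled responses plus a sentinel above the
  maximum: this exhausts all distinct contingency tables, making the search
  exact and invariant to monotone transforms of the responses. Ties are
  broken toward the lowest qualifying threshold.
* **Pairwise added information** is operationalized conservatively as
  $\min_{s \in \mathrm{chosen}} [I(C; f_s, f_c) - I(C; f_s)]$ (the minimum
  over chosen features of the pairwise increment). The minimum, not the
  mean, is used so a candidate redundant with *any* chosen feature gains
  nothing. Because this pairwise quantity can overestimate the true joint
  gain, the *recorded* per-step increment is capped at $H(C)$ minus the
  running total, keeping the cumulative curve within its information bound.
* **Smoothing.** Weights use add-half (Jeffreys) smoothing on all four
  contingency cells, so zero-false-alarm features keep finite weights.
* **Degenerate cases.** A zero-variance cochleagram patch (silence) has NCC
  0 — silence matches nothing; a zero-variance *feature* is a sampling
  degeneracy and is an error at response time; a feature whose responses are
  all identical gets merit 0 and a threshold above all responses. A
  zero-variance patch has complexity (reduced kurtosis) 0 by convention.
* **Features longer than a call** cannot be detected in it; the scoring and
  evaluation pipelines floor their responses at $-1$. The public
  `feature_response()` keeps the stricter contract (error) unless
  `short = "floor"` is requested. This floor is what lets whole-call
  templates compete in the control variants.
* **Coordinates.** Channels are inclusive index ranges; time is in ms with
  half-open windows $[t_{on}, t_{on} + \mathrm{length})$.
* **Streaming events** are threshold crossings of the NCC trace thinned to a
  2 ms refractory period; reconstruction convolves events with an alpha
  kernel ($\tau = 5$ ms — any fixed smoothing constant serves, and the
  placement is corrected for the kernel's peak delay so that a single-MIF
  stimulus reconstructs exactly). Evidence traces normalize by
  $\sum_i |w_i|$ so evidence lies in $[-1, 1]$.
* **Sampling bounds.** Size quotas use strict upper bounds ("less than 1
  octave, less than 100 ms") and inclusive lower bounds. By default one
  third of the pool is reserved for small features so they are well sampled.

## The synthetic corpus

No recorded corpus ships with the package, so a generator
(`generate_corpus()`) emulates the statistical structure that the method
depends on; the generator is first-class, tested code.

Categories (defaults in `default_call_specs()`):

* `twitter_like` — trains of upward linear FM sweeps: ~80 ms phrases
  separated by ~110 ms gaps (~190 ms period), 5-9 phrases, ~1.2 octave
  bandwidth around ~7 kHz.
* `trill_like` — short (~0.5 s) tones with coherent sinusoidal FM/AM at a
  ~30 ms period and 0.7 octave FM depth.
* `other` — a heterogeneous distractor mixture: band-limited noise bursts
  with 15-45 Hz amplitude modulation; long (~1.25 s) tonal calls with slow
  FM and 20-30 Hz vibrato; and "chatter": irregular trains of *slower*
  (120-200 ms) upward sweeps through the same band at irregular (100-300 ms)
  gaps.

Production variability has two levels: per-caller offsets (Gaussian on the
octave scale for dominant frequency, log-normal scales for durations and
intervals) and per-call jitter, both truncated to physical range. All calls
sit on a broadband noise floor at 10 dB SNR.

Three design points matter and were chosen deliberately:

1. **Long-term spectra overlap** across all categories (dominant-frequency
   distributions are interleaved), so spectra alone cannot classify — the
   premise of the method.
2. **Local structure is shared, conjunctions are specific.** Chatter sweeps
   traverse the same band as twitter phrases and the vibrato/AM of the
   distractors occupies the same modulation range as the trill, so *brief*
   fragments are ambiguous; the regular two-phrase ~190 ms conjunction and
   the sustained deep 30 ms modulation remain category-specific. Together
   with the noise floor — whose impact on an NCC shrinks with the number of
   cells a feature averages over — this produces the characteristic
   intermediate-size sweet spot for feature merit.
3. **Between-caller variability dominates within-caller variability** for
   the structured categories (within-caller dominant-frequency sd 0.06-0.08
   octaves versus 0.12 octaves between callers), so a well-placed
   intermediate feature can generalize across all callers, as the reference
   merit profile requires.

What the generator does *not* emulate: harmonic stacks, source-filter
coupling, reverberation, amplitude envelopes of real recordings, or any
perceptual realism. Passing tests on this corpus therefore demonstrate the
*algorithmic* properties (information-optimal selection, generalization
across parameterized production variability, size selectivity, task
specificity) — not performance on real recordings.

## Problem sizes used by the tests and the acceptance script

The reference study conditions (500 + 500 training calls, 6000-feature
pools, 64-channel 1 ms cochleagrams) are the package defaults. The shipped
end-to-end checks run a scaled-down study chosen to exercise every stage at
useful statistical power: 2 structured categories + distractors, 8 callers,
100 train + 100 test calls per class, 500-feature pools, and a 48-channel
front-end spanning 500 Hz-14 kHz at 500 frames/s (2 ms frames — matching
the 2 ms event resolution used downstream). Unit-level checks run on still
smaller fixtures with 32-channel, 4 ms front-ends.

## Control variants

`train_mifs(variant = ...)` re-runs the identical pipeline under the control
configurations: `waveform` (raw-signal templates instead of cochleagrams),
`no_greedy` (top-merit features without redundancy elimination),
`whole_call` (every within-class training cochleagram as one template — the
"grandmother cell" model), `average_call` (a single template: all
within-class cochleagrams aligned to the longest by best NCC lag, then
averaged), and size-constrained pools via `constraints`/`quotas`.
`compare_variants()` applies two-sided rank-sum tests with Bonferroni
correction to their added-information sequences, and
`resample_excluding()` implements the pool-adequacy control (re-selection
after excluding previously chosen MIFs).

## Known limitations

* The gammatone front-end is a stand-in: no adaptation, no
  spontaneous-rate diversity, no middle-ear filtering. Absolute rate values
  are arbitrary units; only their spatiotemporal pattern matters to the NCC.
* Greedy selection with the pairwise-minimum criterion is a heuristic; the
  reported cumulative information is an (H(C)-capped) approximation, not the
  joint information of the selected set.
* Scores of calls in which no MIF is detected are exactly 0, so evidence
  distributions are discrete; ROC operating points move in steps whose size
  shrinks with the number of MIFs.
* The caller-identification task re-uses the identical machinery via
  `task_spec(by = "caller")`; no caller-specific acoustics beyond the
  generator's per-caller offsets are modeled.
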