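# mifcat

Feature-based categorization of animal vocalizations in R.

Classifying vocalizations into call types (or callers) must generalize over
large production variability — different animals emit the "same" call at
different dominant frequencies, bandwidths, durations and rhythms — while
call categories often overlap completely in their long-term spectra, so no
spectral template can separate them. `mifcat` implements a feature-based
answer to this problem for bioacousticians and auditory neuroscientists:

1. **Front-end.** Waveforms become *cochleagrams* — nonnegative
   channels x frames maps of model auditory-nerve firing rates — via a
   gammatone filterbank, half-wave rectification, power-law compression and
   frame averaging.
2. **Random features.** Thousands of random rectangular cochleagram
   fragments are cut from within-class training calls. The response of a
   feature *f_i* to a call is the maximum of the normalized cross-correlation
   (NCC) between the fragment and the call's cochleagram, restricted to the
   fragment's frequency channels: a value in [-1, 1], +1 for a perfect
   match.
3. **Scoring.** Each feature gets an optimal detection threshold θ_i
   maximizing the mutual information I(f_i(θ_i); C) between its binary
   detection and class membership C (the feature's *merit*, in bits; 1 bit =
   perfect binary classification at the balanced reporting prior), and a
   *weight* — the log-likelihood ratio
   log2[ p(f=1|C=1) / p(f=1|C=0) ].
4. **Greedy selection.** Starting from the maximal-merit feature,
   features are added to maximize pairwise added information until the total
   reaches 0.999 bits or the best candidate adds < 0.001 bits. The survivors
   are the *most informative features* (MIFs) — typically a handful to a few
   dozen per category.
5. **Classification.** A novel call's evidence is the weight-weighted,
   normalized sum of MIF detections; sweeping an evidence threshold yields
   ROC/DET curves. Control variants (acoustic-waveform templates, no greedy
   search, whole-call and averaged-call templates, size-constrained pools)
   run through the identical machinery.
6. **Neuron simulation.** Each MIF doubles as a putative feature-selective
   neuron: max NCC acts as a membrane potential V_m and spiking follows the
   rectified power law FR = k·⌊V_m − θ⌋^p (p = 4), giving tuning curves
   over parametric stimulus batteries, natural-vs-reversed preferences, and
   stimulus reconstruction from detection times.

Because no recorded corpus is distributed, the package ships a first-class
synthetic vocalization generator (`generate_corpus()`) with per-caller
production variability and distractors engineered so that long-term spectra
overlap and only intermediate-scale structure is category-specific — the
regime the method is designed for. See the methods vignette
(`vignettes/mifcat-methods.Rmd`) for the model, conventions, and generator
design.

## Worked example

```r
library(mifcat)

# 1. a labeled synthetic corpus: 2 structured call types + distractors,
#    4 callers, caller-stratified train/test split
corpus <- generate_corpus(n_per_class = 30, n_callers = 4, seed = 42)
dplyr::count(corpus, call_type, split)
#>   call_type    split     n
#> 1 other        test     15
#> 2 other        train    15
#> 3 trill_like   test     15
#> 4 trill_like   train    15
#> 5 twitter_like test     15
#> 6 twitter_like train    15

# 2. cochleagrams through the gammatone front-end
fp <- frontend_params(n_channels = 32, cf_min = 1000, cf_max = 12000,
                      frame_rate = 250)
cg_train <- corpus_cochleagrams(corpus[corpus$split == "train", ], fp)
cg_test  <- corpus_cochleagrams(corpus[corpus$split == "test", ], fp)

# 3. learn most informative features for "twitter-like vs everything else"
mifs <- train_mifs(corpus, task_spec("twitter_like"), fp,
                   n_features = 150, seed = 7, cochleagrams = cg_train)
mifs
#> <mif_set> 2 MIFs, total information 1.000 bits (stop: total_target); task: twitter_like
tidy(mifs)[, c("mif_rank", "added_information", "merit", "weight",
               "threshold", "length_ms", "bandwidth_oct")]
#>   mif_rank added_information merit weight threshold length_ms bandwidth_oct
#> 1        1             0.894 0.894   4.32     0.992        24         0
#> 2        2             0.106 0.427   1.38     0.660        40         0.116

# 4. classify held-out calls by weighted evidence
test <- corpus[corpus$split == "test", ]
ev <- evaluate_mifs(mifs, cg_test, test$call_type)
glance(ev)
#>     auc hit_at_fa05 n_within n_outside
#> 1 0.981       0.933       15        30
```

Reading the output: greedy selection stopped after two features because
their combined detections already carry 1 bit — perfect separation of the
*training* set. The first MIF alone has merit 0.894 bits; its weight (4.32
bits) is the evidence one detection contributes. On held-out calls the
two-MIF classifier reaches AUC 0.981, detecting 93% of twitter-like calls at
a ≤ 5% false-alarm operating point — at this toy scale (15 training calls
per class, 150-feature pool) the evidence scale is coarse; the scaled study
run by the acceptance script uses 100 + 100 calls per class and 500-feature
pools.

`autoplot()` methods exist for cochleagrams, ROC curves and evidence traces;
`tidy()`/`glance()` for MIF sets and evaluations. `run_pipeline()` +
`pipeline_config()` orchestrate the whole path (synthesis or a WAV manifest
in; MIF containers, per-feature tables, ROC/DET CSVs and a run log out), and
`inst/cli/mifcat.R` exposes `synth`/`train`/`evaluate`/`stream`/`compare`
subcommands for shell use.

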