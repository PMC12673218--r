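---
title: "Assessing the interpretability of convolutional EEG decoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the interpretability of convolutional EEG decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeginterp)
```

## The question this package addresses

Multivariate decoding of epoched EEG asks which stimulus produced a given
single-trial neural response. Convolutional networks decode well without
assuming fixed response latencies, but their learned features are opaque.
This package implements a complete assessment pipeline for that opacity:
train compact CNN decoders under a leakage-free, participant-wise
cross-validation protocol; extract what they learned with two gradient
attributions (saliency maps and Grad-CAM at early, intermediate, and late
convolutional layers); and quantify *interpretability* as the similarity of
those attribution maps to the EEG signal itself. Because real recordings of
this kind are not openly distributable, a synthetic event-related-potential
(ERP) simulator with planted ground truth stands in for them, which turns
every qualitative claim ("features concentrate at the evoked-response
latency over the stimulated channels") into a testable quantity.

## The decoding protocol

Trials are epoched as channels x samples arrays (microvolts), tagged with a
class and a participant. Cross-validation is *participant-wise*: in each of
5 folds, whole participants are assigned to train (81%), validation (10%),
and test (9%) sets — rounded per set with the remainder to train — so no
participant's trials ever straddle sets and reported accuracy measures
generalization to unseen people. The leakage guard is asserted at training
and at evaluation, not assumed.

Two decoder families are provided.

* **`eegnet_style`** — three convolutions exploiting EEG structure: a
  temporal convolution shared across electrodes (kernel 16 samples), a
  depthwise spatial convolution spanning all electrodes, and a separable
  temporal convolution (kernel 64 samples), each followed by average
  pooling and dropout, then a softmax head. The kernel sizes follow the
  printed study values (16 first, 64 second). The study also prints
  "dropout rate = 4", which is not a valid rate; the package defaults to
  the conventional 0.25. Pooling factors default to 2 and 4 rather than
  the canonical 4 and 8: with a 64-sample separable kernel on 192-sample
  epochs, pooling by 4 first would leave 48 samples — shorter than the
  kernel, which the constructor rejects.
* **`residual_small`** — a reduced residual network (default 4
  two-convolution blocks with identity shortcuts, widening 16 to 32
  filters with a 1x1 projection), global average pooling, softmax head.
  It operates on the electrode vector as convolution input channels, i.e.
  purely along time. A full 18-layer image-style residual network is out
  of scope at desk scale; the reduced network preserves the early /
  intermediate / late layer roles that the attribution analysis needs.

Training minimizes categorical cross-entropy `L = -sum_c t_c log f(y)_c` by
minibatch backpropagation, with early stopping once validation loss has not
decreased for 25 consecutive epochs and restoration of the best-validation
weights. The per-family optimizer defaults follow the published protocol
(SGD, learning rate 1e-4, momentum 0.5, staircase decay 0.94 per epoch for
the EEGNet-style network; Adam at 1e-3 for the residual network; batch 64).
The forward and backward passes are implemented in the package itself
(RcppArmadillo kernels), which is what gives the attribution module exact
access to gradients at the input and at every named layer; every gradient
is verified against central finite differences in the test suite.

Two numerical choices depart from a literal reading of the protocol and are
deliberate:

* **Input scaling.** The networks here carry no batch normalization, so raw
  microvolt inputs put the seeded initialization in a badly scaled regime.
  `train_decoder()` therefore stores a single non-trainable scaling factor
  (1/sd of the training data) on the decoder and applies it at the input;
  it is chain-ruled through saliency, so attribution maps remain gradients
  with respect to the raw input.
* **Demo learning rate.** The published protocol selects learning rates on
  the training and validation sets of its development dataset. Applying the
  same selection to the synthetic data (validation loss only — test sets
  and attribution outcomes were never consulted) gives 0.01 for the
  EEGNet-style network at demo scale; `run_config()` carries that value,
  while `default_train_config()` keeps the published settings.

A time-point-wise multinomial logistic regression
(`pointwise_logreg_baseline()`, ridge penalty 1.0 via `nnet::multinom`,
since the study names no regularization) provides the traditional
decoding baseline; its reported summary is the maximum of the fold-mean
accuracy time course.

## Attributions

For a trial `I` and class `c` with pre-softmax score `S_c`:

* **Saliency** is `dS_c/dI`, a signed channels x samples map of how much
  each input element influences the class score.
* **Grad-CAM** at a convolutional layer weights each feature map `A^k` by
  its globally average-pooled gradient `w_k = (1/Z) sum_ij dS_c/dA^k_ij`
  and combines them as `ReLU(sum_k w_k A^k)`, then resamples to the input
  grid (linear interpolation along time, nearest-neighbor across the
  channel/feature axis). The source text's pooling formula is garbled as
  typeset; the implementation uses standard global average pooling,
  consistent with the text's own definition of `Z` as the number of
  channel-time-point pairs.

`S_c` is the pre-softmax logit, the standard and numerically stabler
choice. The backpropagated class is the trial's true class; since only
correctly predicted trials are attributed, true and predicted coincide.
A layer whose combined map is identically zero (dead gradients, which deep
networks do exhibit) yields a flagged zero map rather than an error.

Aggregation is hierarchical and order matters: trial-level maps are
averaged across trials within participant, then across participants within
fold, then across folds, per experimental condition — so participants with
unequal correct-trial counts weigh equally. Saliency maps are converted to
absolute values at this step (where exactly the absolute value enters is
unstated in the source; trial-level maps stay signed so the user can still
inspect polarity). By default trials from *all* participants are fed back
through each fold's decoder for feature extraction, with a switch to
restrict to held-out participants.

## The interpretability score and its statistics

For each participant, at every sample, the score is the Pearson correlation
*across channels* between the absolute amplitude of the participant's
averaged EEG and their aggregated feature map. The EEG operand is the
average of the same correctly predicted trials that produced the feature
map, keeping both operands on identical trial sets. Per-condition time
courses are averaged per participant before group statistics. Samples where
either vector is constant across channels have no defined correlation and
are excluded (`NA`), not zeroed — setting them to 0 would bias maxima
toward flat segments. This situation is structural, not an edge case:
Grad-CAM maps from layers whose feature maps have no channel extent (the
EEGNet-style network's second and third layers, and all layers of the
purely temporal residual network) are constant across channels after
resampling, and therefore score nothing — the package's analogue of the
near-zero deep-layer scores the study reports.

Group-level inference per sample uses the two-sided one-sample Wilcoxon
signed-rank test against zero with Benjamini-Hochberg FDR correction across
samples. Zero differences are discarded (the common convention; Pratt's
method is not used). For n <= 25 the p-value is exact, computed by
convolving the signed-rank null distribution over (possibly tied, doubled)
ranks — full 2^n enumeration, not the no-ties shortcut; above that, a
normal approximation with continuity and tie corrections. Pairwise
comparisons of per-participant maximum scores (between methods, layers,
and networks) use the paired version of the same test and report a
continuity-corrected z alongside p. The per-participant maximum score
takes the earliest time on ties.

## Topographies

`surface_laplacian()` implements the spherical-spline surface Laplacian
(current source density) with the study's parameters (lambda2 = 1e-5,
stiffness = 4.7), in the source-positive CSD sign convention. It
annihilates spatially constant maps, is linear, and commutes with channel
relabeling — all asserted in tests. The ground-truth-recovery metric reads
the topography of an aggregate attribution map at its recovered peak
latency *after* this transform, mirroring how the study renders
topographic maps ("to emphasize spatial patterns"); without it, the
spatially flat baseline that ReLU leaves in averaged Grad-CAM maps
dominates the raw channel ranking.

## The synthetic-data generator

`simulate_dataset()` generates `participants x classes x trials` epochs:

* each class-specific **component** is a Gaussian time bump (peak latency,
  temporal sd, amplitude in microvolts) times a fixed spatial pattern with
  unit maximum weight — the simplest unimodal ERP surrogate;
* **background noise** is Gaussian white noise shaped to a 1/f^alpha
  amplitude spectrum (alpha = 1), matching broadband EEG without modelling
  oscillations;
* **participant variability** is a multiplicative amplitude factor
  Normal(1, 0.2) and an additive per-channel topography perturbation
  Normal(0, 0.1 x max|pattern|), drawn once per participant — the smallest
  hierarchy that makes participant-wise cross-validation meaningful;
* **trial variability** is a latency jitter Normal(0, 15 ms), truncated so
  the bump stays inside the epoch;
* every trial is common-average referenced per sample.

The default designs: `sim_config_3class()` (three classes, one component
each at 0.15/0.22/0.19 s over six posterior-left / posterior-right /
central channels, 5 microvolt peak, 8 participants, 50 trials per class,
32 channels, 192 samples at 256 Hz over 0-0.75 s) and
`sim_config_prepost()` (a stimulation-free "pre" class versus a "post"
class with a fronto-central component at 0.10 s, 100 trials per class).
The montage is a Fibonacci lattice on the upper unit hemisphere — real cap
coordinates are unnecessary for the mathematics. Noise at 6 microvolts per
channel against 5-microvolt components was chosen once for single-trial
SNR below 1 yet reliable decodability; no public SNR figures exist for the
motivating recordings, so these are plausibility choices, not calibrations.
At this setting the demo decoders reach roughly 0.6-0.8 held-out accuracy —
somewhat above the published range for comparable real data, as expected
for artifact-free simulations with exactly one discriminative component
per class.

`ground_truth_mask()` exposes the planted support (channels with
|pattern| > 0.5, samples within one temporal sd of the peak), which the
recovery tests compare against attribution maps. What passing those tests
shows is that the pipeline recovers *planted, phase-locked, spatially
fixed* evoked activity; it does not show robustness to ocular or muscle
artifacts, induced (non-phase-locked) oscillations, or non-stationary
noise, none of which are simulated.

## Problem sizes

The package's own test and demonstration runs use the 8-participant,
32-channel, 192-sample designs above, with 5-fold cross-validation and
short training schedules (label-permutation controls train for a handful
of epochs, since there is nothing to learn; the recovery demonstration
trains 12 epochs per fold at the demo learning rate). These sizes were
chosen so a complete run remains a desk-scale computation; all of them are
configuration values, and larger studies are a matter of
`run_config(n_participants = ..., trials_per_class = ..., max_epochs = ...)`.

## Known limitations

* The residual decoder is one-dimensional over time; its Grad-CAM maps
  carry no channel structure, so its layer-wise interpretability scores
  are undefined under the across-channel correlation (saliency still
  scores, since input gradients always have channel structure). The
  network-versus-network score comparison is therefore only available for
  maps with channel extent.
* No batch normalization; the input-scaling layer replaces it only
  partially, and very deep configurations may train poorly.
* The Wilcoxon/FDR machinery tests each sample marginally;
  cluster-based permutation statistics are out of scope.
* HDF5 containers store `/data` at float64 so that write-then-read is
  bit-identical.

## A short worked example

```{r example, eval = FALSE}
library(eeginterp)

cfg <- run_config(seed = 1, layers = "early", max_epochs = 12)
report <- run_pipeline(cfg)
print(report)
write_report(report, "report")
```

The printed report shows per-fold held-out accuracies, per-map maximum
interpretability scores with group significance counts, and the
ground-truth-recovery table (latency error in seconds and planted-channel
overlap of the top five CSD channels). `scripts/acceptance.R` recomputes
the label-permutation chance-level controls from scratch.
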