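---
title: "Decoding spike trains with voltage-regulated Tempotron learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding spike trains with voltage-regulated Tempotron learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiketempo)
```

## The decoding problem

A bioelectronic nose reads stimulus identity directly from the spiking of
mitral/tufted cells recorded in the olfactory bulb. The data are small by
machine-learning standards: on the order of ten recorded units, a few
stimulus classes, some tens of presentations per class, each a few seconds
long. Two families of decoders compete here. Bin-based decoders count
spikes in fixed windows and hand the counts to a conventional classifier;
they are robust but blind to spike timing finer than the bin. Spiking
decoders consume the spike times themselves.

spiketempo implements both families around one data container: an event
tibble (`trial_id`, `channel`, `time`, `label`) with dataset-level
metadata (channel count, common trial duration, ordered class labels,
per-trial label table) carried in attributes. Time zero is stimulus onset
and all spike times are nonnegative offsets below the trial duration;
pre-stimulus activity is out of scope.

## Membrane model

An input spike at `t_i` contributes the double-exponential postsynaptic
potential `K(dt) = V0 (e^{-dt/tau} - e^{-dt/tau_s})` for `dt >= 0` and
nothing before it arrives. `V0` is computed from the closed-form peak lag
`t_peak = tau tau_s / (tau - tau_s) * log(tau / tau_s)` so the kernel peak
is exactly 1; `normalizer_v0()` rejects `tau <= tau_s`, where the kernel
has no positive peak. An output neuron's voltage is the weighted sum of
PSPs plus the resting potential (`v_rest = 0` by default) and the neuron
fires when the voltage exceeds `theta = 1`. Output neurons fire at most
once per trial, and no post-spike reset is modelled: the learning rules
below only need the *unshunted* voltage maximum and its time, so reset
dynamics would add state without changing any decision.

### Finding the voltage maximum

The voltage is smooth between spike arrivals but its global maximum
generally falls between evaluation points. `max_voltage()` therefore scans
a grid made of all spike arrival times plus a uniform 1 ms mesh (both
configurable) and then refines the best bracket with a local
golden-section/parabolic search (`stats::optimize`, tolerance 1e-6 s).
Ties in the grid argmax resolve to the earliest time, which keeps results
deterministic. Training and prediction use the grid values without the
local refinement: with `tau_s` at least an order of magnitude above the
mesh, the refinement changes voltages by far less than any threshold
decision, and skipping it lets one matrix product evaluate all output
neurons on a whole trial at once.

## Learning rules

Output neurons are organised as one group of `group_size` neurons per
class (default 5; the within-group index pairs the n-th neuron of every
group). Weights start from a seeded Gaussian with sd `init_scale = 0.01`,
small enough that every neuron starts below threshold.

**Classic rule.** Error-gated: on each presentation, a silent target-group
neuron gains `lambda * sum_{t_i < t_max} K(t_max - t_i)` per channel, a
firing non-target neuron loses the same quantity, and a correctly behaving
neuron is untouched. An epoch that produces no errors therefore changes
nothing, and training stops as converged.

**Voltage-regulation rule.** Every neuron is updated on every
presentation. For each within-group index the groups' maximal voltages are
transformed by the softplus `f(V) = log(e^V + 1)` (always positive, so the
voltage share `f(V_t) / sum_m f(V_m)` is well defined), and the classic
update is multiplied by the derivative of the log share: positive for the
target group, strictly negative for the others. The same-trial effect is
one-sided by construction — because all kernel sums are nonnegative, the
update can only raise the target neuron's maximal voltage and only lower
the others' — which is verified as a property test. Updating on *every*
presentation, not only on errors, is the point: with small training sets
the error-gated rule stops as soon as the thresholds are barely cleared,
leaving margins that trial-to-trial jitter can breach. We read the rule's
description this way deliberately; the alternative (regulated updates only
on error trials) can be recovered by composing `vr_factor()` with an
external gate, but it is not what the training loop does.

Training presents trials in a seeded shuffled order, records training
accuracy each epoch, stops at `max_epochs`, on classic convergence, or
after `early_stop_patience` epochs without improvement, and returns the
weights with the best training accuracy seen (the final weights are also
kept on the fitted object). Prediction counts firing neurons per group;
ties — including the all-silent case — go to the group with the larger
summed voltage maximum, then to the lower class index.

## Bin-based baselines

`bin_features()` counts spikes in half-open bins of width `bin_size` over
`[0, period)` and concatenates channels channel-major; a 0.5 s bin over a
5 s window gives 10 features per channel. The window must divide evenly by
the bin, avoiding partial-bin ambiguity. On top of the features sit thin
adapters over standard implementations — decision tree (rpart), k-nearest
neighbours (class), LDA (MASS), linear and RBF SVM (e1071) — plus a
diagonal-Gaussian maximum-likelihood classifier implemented here: per
class and feature a mean and variance (floored at 1e-6 so constant
features are harmless), classification by summed log density. The diagonal
model is deliberate: with `channels x M` features and sixteen training
trials per class a full covariance is singular.

## Evaluation protocols

`random_test_protocol()` repeats a seeded stratified split
(`train_per_class` trials per class train, the rest test; the recorded
defaults give the 16/4 split repeated 100 times), trains the decoder
fresh, and records test accuracy. A master seed spawns one substream per
repetition, so different decoders evaluated under the same seed see
identical splits and are paired. `cv_select()` implements hyperparameter
selection by a stratified 20% holdout of the training set (grid winner
refit on the full training set; ties to the earlier grid entry) — the
package applies it to `tau` via `default_tau_grid()` (0.05–1 s with
`tau_s = tau/4`, the customary ratio), to `k` for KNN, and to cost/gamma
for SVMs. `run_sweep()` varies one axis: bin width; training-set size in
sample groups (a group is one random trial from every class, the remainder
tested); or observation window, truncating *both* training and test trials
— a deployed quick detector only ever sees the short window, so training
on the full trials would leak information the detector cannot have.

## The synthetic generator

Real rat olfactory-bulb recordings of this shape are not redistributable,
so `generate_synthetic()` emulates their structure: per class and channel
a fixed latency template (`template_spikes_per_channel` times drawn once
from Uniform(0, duration)), re-emitted each trial with Gaussian jitter
(default sd 10 ms, clipped to the trial window rather than wrapped), on
top of homogeneous Poisson background spikes (default 5 Hz — sparse,
stimulus-locked firing, the regime in which timing codes matter). Defaults
mirror a single-animal session: 11 channels, 4 classes, 20 trials per
class, 5 s trials. With `rate_contrast = 0` every class has the same
expected count per channel, making the data separable *only* through
timing; `rate_contrast > 0` adds class-dependent Poisson rates. Exact
duplicate times after jitter are nudged up by 1 µs to keep spike trains
strictly increasing. The same seed reproduces a dataset bit-exactly.

What the generator does not emulate: breathing-cycle phase locking,
inter-trial drift and adaptation, correlated noise across channels, odor
concentration effects, and unit instability across days. Passing tests on
this benchmark therefore demonstrate that the implementation learns timing
structure under realistic counts and jitter — not that any accuracy level
transfers to a particular animal. One visible consequence: the latency
templates are coarse enough that sub-second bin counts partially encode
them, so fine-binned baselines do well here, while single-bin (pure-rate)
features are provably uninformative and stay at chance. The discriminating
comparison on timing-only data is against the single-bin baseline.

## Numerical and design choices

* Voltage grid 1 ms by default (2 ms in the quick test settings), always
  augmented with the spike arrival times; refinement tolerance 1e-6 s.
* `lambda = 5e-3` default learning rate; large enough to cross threshold
  in a few epochs at these spike counts, small enough not to oscillate.
* Natural logarithms throughout the regulation factor; its numerically
  safe evaluation uses `log1p(exp(V))` with a linear tail above `V = 30`
  and the logistic function for `f'`.
* Problem sizes in the test suite are chosen for desk-scale runs: 2 s
  trials, 10–12 trials per class, group size 3, at most 25 epochs, and
  20 paired repetitions for rule comparisons. These sizes already show the
  voltage-regulation advantage clearly.
* File format: plain CSV with `#`-header metadata and one row per spike,
  times printed to 12 significant digits so round trips are lossless;
  trials without spikes are declared in `#trial=` header lines.
* Labels are strings on disk and in tibbles; dense class indices (file
  header order) are used only inside the training loop.

## Limitations

The training loop is pure R; it is comfortable at the package's native
problem sizes (seconds per model) but not at thousands of trials or
channels. Only single-spike output coding is implemented — each output
neuron is read as fired/silent per trial — and no multi-spike Tempotron
extensions. Hyperparameter search is a plain holdout grid, not nested
cross-validation, mirroring the small-data protocols the package targets.
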