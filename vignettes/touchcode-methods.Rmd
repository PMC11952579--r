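---
title: "Decoding social touch from single-afferent spike trains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding social touch from single-afferent spike trains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

When a person taps, strokes or holds another person's forearm to convey a
social message — attention, happiness, calming, love, gratitude, sadness —
how much of that message is already present in the spike train of a *single*
peripheral mechanoreceptive afferent? `touchcode` implements the full
analysis pipeline for this question: firing-feature extraction, rate-coding
and temporal-coding classification under repeated stratified
cross-validation, most-informative-segment identification by sliding
windows, saturation window-length estimation, and spike-timing jitter
sensitivity. Because microneurography recordings are scarce, the package
ships a synthetic spike-train generator that emulates the contact rhythms of
the six standardized expressions passed through response models of six
afferent subtypes (Field, HFA, FA-II, SA-II, CT, MS), so that every protocol
is testable end to end.

## Data model

A trial is a `spike_train`: integer spike times in milliseconds on the
half-open interval `[0, 10000)` (trials are cropped to the first 10 s at
1 ms resolution), plus unit, subtype and expression labels. Instantaneous
firing frequency (IFF) is the reciprocal of the backward inter-spike
interval, in Hz, assigned at the later spike; the first spike of a train
carries no IFF, and trains with fewer than two spikes have an empty IFF
series whose summary statistics are defined as 0 so that feature vectors
are total (no NaN ever reaches a classifier).

The *step-interpolated* IFF trace expands the series onto the 1 ms grid:
zero before the second spike, the IFF value of spike *i* held on
`[t_i, t_{i+1})`, and the last value held to trial end. The hold-forward
convention is a choice (the alternative, hold-backward, is acausal); it is
applied uniformly everywhere the trace is used (window variation and
entropy metrics).

Duplicate spike times can arise after jitter quantization or in rounded
source data. They are resolved at construction by re-assigning colliding
spikes to the nearest free 1 ms bin (ties toward the earlier bin), which
preserves spike counts and forbids zero-length intervals (infinite IFF).

## Rate coding: five features and a linear SVM

The rate code is summarized by five aggregate features per 10 s trial:
total spike count, mean IFF, peak IFF, IFF variation (coefficient of
variation of the IFF values; defined as 0 below three spikes to avoid 0/0),
and burst count (maximal spike groups separated by inter-spike gaps longer
than 1 s; a non-empty train with no such gap is one burst). For gesture-level
analysis the expressions collapse to tapping (attention, happiness),
stroking (calming, love) and holding (sadness); gratitude mixes tapping and
holding and is excluded.

The classifier is a linear SVM, one-vs-rest with squared hinge loss and
`C = 1` (unspecified in the protocol we follow; fixed for reproducibility).
Since the feature space has five dimensions, the primal objective is
minimized directly with BFGS — deterministic, no stochastic solver.
Features are z-scored with training-fold statistics only, so
cross-validation never leaks test-fold scale.

## Temporal coding: a small 1-D CNN

The temporal code is probed by a one-dimensional convolutional network on
the full binary spike train (10 000 samples at 1 ms). The constraints we
inherit are: five convolutional layers, 0.2 dropout per layer, categorical
cross-entropy, Adam starting at learning rate 0.001 with
reduce-on-plateau, early stopping, and a parameter count of order 10^4.
The exact channel plan behind the original 16,646-parameter model is not
recoverable, so the reference configuration (`cnn_spec()`) uses channels
8–16–16–16–16 with kernel 7, strides chosen automatically so the temporal
axis shrinks to a few dozen steps before global average pooling and a dense
softmax head (≈6.5k parameters). Three numerical choices matter and are
deliberate:

* binary inputs are multiplied by a fixed `input_scale = 10` so first-layer
  pre-activations are of order one despite ~1–3% spike density;
* batches are small (8) because datasets hold tens of trials and Adam needs
  enough update steps per epoch;
* training loss (not a validation split) drives plateau reduction and early
  stopping — with 25–40 training trials per fold a further split would be
  noise; held-out performance is measured only by the CV harness.

All CNN randomness (init, shuffling, dropout) flows from one integer seed
through an internal generator, so training is bit-reproducible.

## Cross-validation protocol

Repeated stratified 5-fold CV throughout: per class, indices are shuffled
and dealt round-robin, so per-fold class counts differ by at most one.
Accuracy pools the held-out predictions of all folds within a repeat, then
averages over repeats; confusion matrices pool all held-out predictions and
are row-normalized. Repeat counts follow the protocol being replicated: 20
for full-train classification, 2 for the window-metric comparison, 7 for
window-length curves, 5 for jitter. Stratification is on the class label
only, matching the protocol's wording; `group_by_unit = TRUE` keeps all
trials of one unit in a single fold for leakage-controlled runs (repeated
trials from one unit are correlated, so label-only stratification can be
optimistic — we implement both rather than guess). Trials are sorted by id
before folding, so results are invariant to input-file order.

## Most informative segments

Window lengths run from 0.1 s to 4 s in 0.1 s steps and from 4 s to 10 s in
0.25 s steps — 64 lengths. For each length, five candidate positions are
found by sliding at 1 ms steps: the first window, and the argmax windows of
spike count, mean IFF, IFF variation and IFF entropy (ties to the earliest
start, which also makes the degenerate empty-train case well defined).
Mean IFF inside a window counts only intervals whose *both* spikes lie in
the window, avoiding attribution of boundary-straddling intervals.
Variation and entropy are computed from the step-interpolated IFF within
the window; the entropy estimator is a fixed-width histogram (5 Hz bins,
zero rates in the zero bin, natural log) because the source protocol does
not define one — the bin width is exposed as a parameter. All four scans
are O(duration) sliding computations in compiled code.

Metric comparison uses two-sided Mann–Whitney U tests on per-length mean
accuracies for each metric pair with Benjamini–Hochberg correction; the BH
step-up rule is implemented directly and property-tested against the
reference implementation.

## Saturation window length

Accuracy-vs-length curves (averaged over the best two position metrics) are
fitted with an ordinary least-squares fourth-order polynomial; the fitted
maximum is located by a 1 ms scan over the grid span and the saturation
length is the smallest length whose fitted accuracy reaches 90% of that
maximum *and stays at or above the threshold through the maximum's
location*. Both the maximum and the crossing are read off the fitted curve
(raw maxima are noisy; the guard clause removes spurious early crossings
from quartic wiggle — an edge case the source protocol leaves open).
Lengths are rescaled to seconds before fitting for conditioning of the raw
quartic. The estimator is scale-invariant in accuracy by construction.

## Spike-timing jitter

Each spike time receives independent zero-mean Gaussian noise of SD 0–100 ms
(5 ms steps by default), is rounded to the grid and clipped into the trial
(clipping, not deletion: deleting would confound timing noise with rate
loss); collisions go to the nearest free bin, so spike counts are conserved
at every SD. The classifier is trained per CV split on clean training folds
and evaluated on jittered test folds, ten independent noise sets per SD
(one noise-free evaluation at SD 0, which therefore reproduces the clean
baseline exactly — a protocol identity the tests assert). Every noise cell
is seeded as a function of (base seed, SD index, set index, repeat, fold),
so any cell can be reproduced in isolation.

## The synthetic generator: what it emulates, and what it does not

Contact mechanics are abstracted into three channels on the 1 ms grid —
vertical impact, tangential motion, static pressure, in arbitrary units —
because the recordings this design mirrors include no contact forces or
kinematics. Expression rhythms implement the standardized choreography:
attention is 4 bursts of 4–5 taps (~1.5 s bursts, ~1 s gaps); happiness is
continuous random tapping; calming is 4 slow ~2 s strokes with ~0.5 s gaps;
love is continuous back-and-forth stroking; gratitude alternates ~2 s pat
bouts (3–4 pats) with ~2 s holds; sadness is one sustained hold spanning
the trial. Bout boundaries get Gaussian timing jitter (default SD 100 ms)
between trials.

Subtype models turn the channels into an instantaneous rate
`λ(t) = clip(baseline + Σ gain·g(channel), 0, cap)`:

* **SA-II-like** (sustained decay): static drive decays as
  `exp(−t′/2500 ms)` within each bout — sustained, slowly decaying firing
  to holds.
* **HFA-like / FA-II-like** (transient): every channel is replaced by its
  smoothed rectified derivative, so sustained contact itself elicits
  nothing and holds produce onset/offset pulses only. (A stated
  "zero static gain" for HFA is implemented behaviorally — zero *sustained*
  static response — because a literally zero coefficient would also remove
  the onset/offset response the same contract requires.)
* **Field-like**: proportional response to movement channels, none to
  static pressure.
* **CT-like / MS-like**: low-rate, with a 20 ms refractory period so that
  the ~50 Hz rate ceiling also bounds every IFF value (with a 1–2 ms dead
  time the mean of reciprocal ISIs of a capped Poisson train would still
  exceed 150 Hz). CT favors the tangential channel; MS couples weakly to
  everything over a 10 Hz proprioceptive baseline.

Spikes are drawn by Bernoulli thinning on the grid with an absolute
refractory period (spike allowed when `t − last > refractory`); for
constant rate the expected count follows the dead-time-corrected renewal
rate `λ/(1 + λτ)`, which the tests verify against 500 Monte-Carlo
replicates. Units get one log-normal gain multiplier each (SD 0.25),
making repeated trials from a unit correlated, which is what makes
cross-validation honest to test.

Amplitudes and gains are free parameters. They were calibrated once to the
qualitative contrasts the design targets — slowly-adapting sustained firing
through holds, transient-only hold responses in fast adaptors, mean IFF
decreasing from tapping to stroking to holding in Aβ subtypes, IFF ≤ 50 Hz
in CT/MS, and a decoding rank order with SA-II-like and HFA-like well above
CT-like and MS-like (the first CT parameterization was as decodable as HFA
and was weakened accordingly). A green test therefore establishes that the
*pipeline* behaves as specified on data with the right structure; it does
not establish the empirical accuracies of real microneurography data, whose
headline numbers (70–80% for SA-II/HFA, saturation near 3.3–5 s, jitter
tolerance 10–20 ms) are not reproducible from synthetic inputs and are not
asserted anywhere.

## Known limitations

* The CNN matches the stated architectural constraints but not the original
  parameter count, which is unrecoverable.
* Accuracy averaging (pool folds within repeat, then average repeats) is
  one of two defensible readings of the protocol; the other (pool
  everything) coincides for balanced folds.
* The generator has no receptive-field geometry, no inter-channel
  correlation structure, and no biophysics; CT afferent fatigue and
  after-discharge are not modeled.
* `jitter_protocol` evaluates the CNN only, as in the protocol it follows;
  jittered SVM features can be obtained by composing `add_jitter` with
  `feature_table`.
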