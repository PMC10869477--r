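---
title: "Cross-subject seizure prediction with adversarial domain adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject seizure prediction with adversarial domain adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epileptic seizures are preceded by a *pre-ictal* period during which scalp
EEG departs from the *inter-ictal* baseline. A seizure predictor is therefore
a binary classifier over short EEG windows: pre-ictal (positive, an alarm
horizon before the seizure) versus inter-ictal (negative). The clinically
hard part is not within-patient classification — it is generalization.
EEG differs markedly between patients (electrode impedances, skull geometry,
background rhythms, the spectral signature of the pre-ictal state itself), so
a classifier trained on a pool of patients degrades sharply on a patient it
has never seen. This package implements, end to end, one response to that
problem: a compact convolutional classifier trained jointly with an
adversarial *domain discriminator* so that the learned features become
invariant to the patient while staying discriminative for the pre-ictal
class.

Three evaluation regimes are distinguished throughout:

* **multiple-subject**: all patients' windows are pooled and split into
  train/validation/test — the optimistic regime;
* **cross-subject (LOPO)**: leave-one-patient-out — train on N−1 patients,
  test on the held-out one;
* **cross-subject with adaptation**: as LOPO, but the held-out patient's
  *unlabeled* windows participate in training as the target domain.

## Preprocessing

`preprocess_config()` encodes the conventional recipe, each step exposed as
its own function:

| step | function | default |
|---|---|---|
| mains notch | `apply_filters()` | 50 Hz, Q = 30 biquad, zero-phase |
| band-pass | `apply_filters()` | 0.5–70 Hz, 4th-order Butterworth, zero-phase |
| pre-ictal horizon | `label_intervals()` | 3600 s before each onset |
| ictal + post-ictal exclusion | `label_intervals()` | onset→offset, plus 3600 s guard |
| windowing | `extract_windows()` | non-overlapping 10 s, floor rule |
| normalization | `normalize_windows()` | per channel, zero mean / unit sd |
| class balance | `balance_undersample()` | random majority under-sampling |

Both filters are applied forward–backward (`signal::filtfilt`), so no phase
shift is introduced; the notch is a standard RBJ biquad and the band-pass a
second-order Butterworth section (4th order overall). Only the cutoffs are
fixed by the protocol; the realization is the conventional EEG choice.

The post-ictal exclusion *duration* is a genuinely open parameter: the
protocol requires post-ictal data to be excluded but names no length. We
default to 3600 s, symmetric with the pre-ictal horizon and consistent with
the hour-scale exclusions used by related work; it is a config field, not a
constant. Interval labelling resolves overlaps by priority
excluded > pre-ictal > inter-ictal, so a pre-ictal horizon that would reach
into an earlier seizure's exclusion zone is clipped there.

Two more open points and how we resolved them:

* **Balance before or after splitting?** Under-sampling before splitting
  lets discarded majority windows leak design information into the test set
  composition. Default: split first, balance the training set only
  (`balance_before_split = TRUE` restores the other reading).
* **Resampling across datasets.** Recordings keep their native sampling
  rate; the model's `T` is `window_s * fs`, so 256 Hz and 512 Hz cohorts get
  models with different `T` rather than silently resampled data.

## The classifier

The network is a three-block compact CNN over a `(C, T)` window
(`model_config()`, `build_model()`):

1. **Temporal block** — `F1` linear convolutions with kernel `(1, 128)`
   (half a second at 256 Hz), no bias, batch-normalized: learned frequency
   filters.
2. **Spatial block** — a depthwise convolution with kernel `(C, 1)` and
   multiplier `F2` (no bias), batch norm, ReLU, average pooling `(1, 16)`,
   dropout: learned spatial patterns per frequency filter, in the spirit of
   filter-bank CSP.
3. **Feature block** — the `F2·F1` maps are folded into the spatial axis of
   a single map, then `F3` convolutions with kernel `(1, 64)`, batch norm,
   ReLU, pooling `(1, 16)`, dropout.

A dense softmax layer closes the stack. The flattened embedding
`phi(x)` has dimension `F3·F2·F1·(T/256)` and is exposed by `forward()`
alongside the class probabilities — the adaptation heads consume it.

Parameter counts are closed-form and tested: `128·F1`, `2·F1`, `C·F2·F1`,
`2·F2·F1`, `64·F3`, `2·F3`, plus `(d+1)·2` for the dense layer. Two design
points deserve a note:

* **The third convolution.** A plain convolution over `F2·F1` input maps
  would carry `64·F3·F2·F1` weights; the published count for this
  architecture family is `64·F3`, which is only consistent with reshaping
  the `F2·F1` maps into the spatial axis of a *single* map before
  convolving. We adopt that reading; it reproduces both the parameter count
  and the printed output shape `(F3, F2·F1, T')`.
* **No convolution biases.** The printed counts admit none; batch norm
  supplies the affine shift.

Defaults `F1 = 8, F2 = 2, F3 = 16, dropout 0.25` follow the compact-CNN
convention of this architecture family (the source protocol does not state
them); all are config fields.

### The engine

No deep-learning framework is available to this package, and the training
dynamics *are* the scientific content, so the forward and backward passes
are written out explicitly (R with two small C++ kernels for the
convolutions). The architecture is fixed, which makes manual
backpropagation tractable and auditable; every gradient path is pinned by
finite-difference tests at tolerance 1e-6, and the convolutions are
additionally checked against naive nested-loop oracles. Batch normalization
uses biased batch variance with eps 1e-5 and running-statistics momentum
0.1; evaluation mode uses running statistics and disables dropout, so
inference is deterministic and per-example. ADAM is implemented with the
standard bias correction (eps 1e-8).

## Domain adaptation

All three methods are feature-based adversarial games between the encoder
`phi` and a discriminator `D` (an MLP, default 128–128, sigmoid output)
that predicts the domain (source = 0, target = 1):

* **DANN** — `D` sees `phi(x)`. The total objective is
  `L_task − λ·L_domain` for the encoder and `+L_domain` for `D`; the single
  sign flip is implemented by the gradient reversal layer
  (`grad_reverse()`), whose forward pass is the identity and whose backward
  pass multiplies the upstream gradient by `−λ`.
* **CDAN** — `D` sees the multilinear map `phi(x) ⊗ F(phi(x))`
  (`multilinear_map()`), i.e. alignment is conditioned on the classifier's
  prediction. With two classes the full `d·c` map is always used; the
  randomized low-rank approximation used for large label spaces is
  unnecessary here.
* **CDAN+E** — each example's discriminator term is weighted by
  `1 + exp(−H(p))` (`entropy_weight()`), in `[1.5, 2]` for two classes, so
  confidently classified examples drive alignment.

Conventions we had to fix (and test):

* **Loss bookkeeping.** The domain loss is the per-side batch mean of the
  binary cross-entropy, the two sides summed; an uninformative
  discriminator emitting 0.5 scores exactly `2·ln 2`.
* **Detachment.** The class probabilities entering the multilinear map and
  the entropy weights are treated as constants (no gradient flows back
  through them), matching the reference implementation of conditional
  adversarial adaptation. Entropy weights are used raw, not batch-
  normalized.
* **Separate per-domain forward passes.** Source and target batches pass
  through the encoder separately, each with its own batch statistics. This
  makes `λ = 0` *exactly* equal to supervised training on the source batch
  — a property the tests assert bitwise through an optimizer step.
* **λ schedule.** The protocol names no λ; we default to the sigmoidal ramp
  `λ(p) = 2/(1+e^{−10p}) − 1` over training progress, standard in the
  adversarial-adaptation literature, with a constant-λ override
  (`train_config(lambda_mode = "constant")`).
* **Transductive target use.** In LOPO with adaptation, the held-out
  subject's unlabeled windows are used for adaptation and subsequently
  scored (the natural reading of "unlabeled data from a new patient");
  `run_lopo(transductive = FALSE)` adapts on one half and scores the other.
* **Early stopping** monitors the *source* validation loss — target labels
  do not exist by definition, so no target-side criterion is admissible.

Training follows the stated protocol: ADAM at learning rate 0.005 with
β = (0.9, 0.999), at most 500 epochs, early stopping after 20 epochs without
validation-loss improvement (operationalized as improvement > 1e-4, a
tolerance the protocol leaves unstated), best-validation weights restored.
Batch size defaults to 64 (also unstated upstream; exposed in
`train_config()`).

## The synthetic cohort

Real seizure corpora are multi-gigabyte downloads; the package instead ships
a generator (`generate_cohort()`) whose *ground truth is known*, so every
pipeline stage and both qualitative findings are testable offline. Each
subject's signal is a sum of per-channel pink noise, a subject-specific
narrow-band oscillation at an alpha-like peak (8–13 Hz), and a band-limited
component in a pre-ictal band (centre 16–24 Hz), mixed across channels by a
random orthonormal matrix, plus white sensor noise. During the pre-ictal
span before each annotated onset, the in-band component of the *whole*
signal is multiplied by `preictal_gain`, so band power rises by exactly
`preictal_gain²` in expectation — a contract the tests verify with a
periodogram oracle. Ictal intervals carry a high-amplitude broadband burst
whose only purpose is to exercise the exclusion logic; waveform realism of
seizures is a non-goal.

Domain shift is a dial: `shift_strength` in `[0, 1]` scales the between-
subject dispersion of the peak frequency, background gain, pre-ictal band
edges, gain, noise level, and of the mixing matrix (an orthonormal blend
between a cohort-shared and a subject-specific matrix). At 0, subjects are
identically distributed; at 1, a classifier trained on one subject transfers
poorly to another — the property the cross-subject experiments need. Seeds
are hierarchical (master seed → per-subject seeds by index), so adding a
subject never changes earlier subjects' data.

What the generator does *not* emulate: ocular/muscular artifacts,
non-stationary drift, electrode pop, realistic seizure morphology, and the
heavy class imbalance of clinical recordings (imbalance exists — more
inter-ictal than pre-ictal time — but not at clinical ratios). Passing the
package's tests therefore demonstrates that the *method and its
implementation* behave as published under controlled shift, not that any
particular clinical accuracy would be attained; the EDF path exists so real
cohorts can be run with the same code.

## Problem sizes used by the tests and the acceptance script

The end-to-end checks run a deliberately small study, chosen once as the
package's desk-scale conditions: 6 subjects, 4 channels at 256 Hz, 280 s
records with one seizure and a 100 s pre-ictal span, one-second windows
(~100 pre-ictal + ~140 inter-ictal per subject before balancing), a small
model (`F1 = 4, F2 = 2, F3 = 4`, kernels 64/32, `T = 256`), 6 training
epochs, batch 64, and 5 replicate seeds (3 in the acceptance script). At
this scale the pooled model reaches ≥ 0.9 test accuracy, the LOPO baseline
drops well below it, and each adversarial method recovers a median share of
the gap — the same ordering the published study reports at clinical scale,
which is what these checks assert (direction and ordering, not the printed
clinical numbers, which require the real PhysioNet cohorts).

## Numerical and degenerate-case decisions

* Constant channels normalize to all-zeros rather than NaN.
* Single-class truth vectors flag threshold metrics/AUC as undefined (`NA` +
  a flag) instead of silently reporting 0.
* AUC uses midranks, so ties contribute ½ and the value equals
  `P(s⁺ > s⁻) + ½P(tie)` exactly; the tests compare against an exhaustive
  pairwise oracle at 1e-12.
* The decision threshold for confusion-based metrics is 0.5 on the
  pre-ictal probability (unstated upstream; exposed as an argument).
* LOPO summaries report the population standard deviation across subjects,
  matching the "mean ± sd" convention of per-patient result tables.
* "Same" padding for even kernels pads `(k−1)/2` left (floor) and the rest
  right.
* EDF output quantizes to 16 bits over a symmetric integer physical range;
  round trips are exact to that quantization and idempotent afterwards.

## Known limitations

* The engine is CPU-bound and single-threaded; clinical-scale training (tens
  of thousands of 10 s windows, `F1 = 8/F3 = 16` models) is feasible but
  slow — the design target is correctness and auditability at desk scale.
* EDF+ annotation channels are not parsed; seizure times travel in the CSV
  sidecar schema (a CHB-MIT summary-file normalizer is included).
* No artifact rejection, montage re-referencing, or channel interpolation.
* Statistical significance testing of method differences is out of scope
  (none is performed upstream either).
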