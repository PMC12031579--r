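---
title: "How polycss scores a comparison-question polygraph test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How polycss scores a comparison-question polygraph test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a comparison question test (CQT), an examinee answers *relevant*
questions (about the incident under investigation), *comparison* questions
(similar but unrelated, used as a psychological control) and *irrelevant*
baseline questions while five physiological channels are recorded:
photoplethysmogram (PPG), blood pressure, thoracic respiration, abdominal
respiration and skin conductance, all sampled at 40 Hz. The working premise
of the CQT is that a deceptive examinee shows stronger sympathetic-arousal
responses to relevant than to comparison questions, whereas a truthful
examinee responds at most as strongly to relevant questions.

An examination is organized as a *series* of three *charts* (recording
passes), each chart containing three (comparison, relevant) question pairs —
nine *question sets* per series. `polycss` assigns each question set a
deception probability with a neural network, sums the nine probabilities of
a series into a score in $[0, 9]$, and issues a three-way decision:
deception, non-deception, or inconclusive.

## Preprocessing: windows and the offset join

For each question set, a 22.4 s window (896 samples) is cut from every
channel at the comparison-question onset and at the relevant-question onset
(comparison first). The two windows are concatenated per channel after
shifting the second by a constant so that its first sample equals the last
sample of the first window — the *offset join*. This removes the artificial
step discontinuity at the boundary between two separately recorded
responses while preserving all within-window dynamics; it is exactly
translation-equivariant, so absolute channel baselines never influence the
joined shape. The joined 1792-sample segment is then z-standardized per
channel (constant channels map to zeros), making the simulator's or
device's arbitrary units irrelevant to the classifier.

Two conventions here were genuinely open and are our choices: windows start
at *question onset* (answer onsets are not modelled), and no filtering or
detrending precedes the network. Onsets are converted to sample indices by
`floor(onset_s * 40)`, a reproducible convention.

**Why 22.4 s?** The field's numerical scoring systems evaluate reaction
windows of 10–20 s; we use 20 s of response plus a 2.4 s margin. The exact
value is reverse-engineered from the network geometry: with four valid
convolutions (kernels 70/50/30/10) each followed by a size-2 max pool, a
1792-sample input is the length that emits exactly 89 time steps, the
documented sequence length entering the LSTM. It is kept as a single named
constant (`css_question_window()`); changing it breaks the geometry check
loudly at configuration time.

## The classifier

Each of the five channels feeds its own weight-independent branch (five
CNNs, not shared weights) of four blocks:
convolution (valid, stride 1, kernel sizes 70/50/30/10, filter counts
70/50/30/10, ReLU) → max pool (size 2, stride 2, flooring odd lengths) →
dropout (50 %, 50 %, 25 %, 25 %). The sequence-length chain is
$1792 \to 861 \to 406 \to 188 \to 89$, asserted at build time. Branch
outputs ($89 \times 10$ each) are concatenated along the feature axis into
$89 \times 50$; a single LSTM layer (50 tanh units, returning every time
step) maps this to $89 \times 50 = 4450$ flattened features, classified by
a 50-unit ReLU layer and a 2-unit softmax. The scalar the rest of the
system consumes is always the softmax mass of the deceptive class.

Training minimizes the mean softmax cross-entropy with Adam
(learning rate 0.0015, batch size 64 by default). Weight filters start from
random noise: He-scaled normals for the ReLU convolutions and first FC
layer, Glorot-uniform for the LSTM and softmax layers, LSTM forget-gate
bias 1. The implementation is our own (im2col + BLAS convolutions,
backpropagation through time, Adam) in RcppArmadillo; every random draw —
initialization, epoch shuffling, dropout masks, the validation split —
comes from R's RNG, so a single `set.seed()` reproduces training exactly
(inference disables dropout and is deterministic).

Several placement details are unstated in the architecture's public
description and were fixed as follows: convolutions are un-padded
(“valid”) with stride 1 — the only choice that reproduces the 89-step
chain; dropout sits after each pooling step and acts only in training;
the merge is feature-axis concatenation — the only merge consistent with
five 10-filter branches feeding an $89 \times 50$ LSTM output. Epoch
budget and early stopping are likewise unstated; the default is at most
100 epochs with patience 10 on the loss of a 10 % validation split carved
from the training data (`validation_fraction = 0`, used throughout the
test suite, disables the split and trains for exactly `max_epochs`).
Shallower ablations (1–3 conv layers, or CNN-only without the LSTM)
remain constructible through `arch_config()`, but the shipped default is
the full 4-layer + LSTM structure.

## Scoring and the inconclusive band

The nine out-of-network probabilities of a series sum to a score
$s \in [0, 9]$. Decision thresholds come from the Utah numerical scoring
scale, on which three relevant questions over three charts contribute
±2 points each (total ±18) with ±6 as the deception/truth cut-offs. A
cut-off $c$ maps affinely onto the score range:

$$\mathrm{threshold} = \frac{c - (-18)}{18 - (-18)}
  \times (\mathit{score}_{\max} - \mathit{score}_{\min})
  + \mathit{score}_{\min},$$

giving threshold 1 = 6 (deception) and threshold 2 = 3 (truth) with the
defaults. The decision is *deception* for $s > 6$, *non-deception* for
$s < 3$, and *inconclusive* otherwise; boundary values fall in the
inconclusive band, the conservative reading of “above”/“below”. The
formula keeps $\mathit{score}_{\min}$ explicit so other score ranges can
reuse it; with the defaults it reduces to the two constants above.

## The synthetic-data generator

Real CQT recordings are not publicly available, so the package ships a
generator whose defaults *are* its study conditions. One chart is 240 s:
an irrelevant question at 5 s, then three pairs at onsets 20/45, 70/95,
120/145 s (comparison always 25 s before its relevant question). Each
question elicits an arousal impulse whose amplitude is 1 (comparison,
log-normal jitter sd 0.15), $1 + \mathit{effect\_size}$ (relevant,
deceptive condition) or 0.8 (relevant, truthful), 0.3 for the irrelevant
question. Channel responses follow standard sympathetic phenomenology:
skin conductance rises by a bi-exponential transient (rise 0.75 s, decay
4 s, gain 1.5 over a tonic level of 8); pulse amplitude and both
respiration amplitudes are suppressed by arousal-proportional fractions
(slower kernels, 1.5 s/8 s); blood pressure rises slowly (2 s/10 s). All
responses start 1.5 s after onset; white noise (`noise_sd`, default 0.1)
and random-walk drift (`drift_sd`, default 0.05) are added per channel,
scaled to each channel's nominal response size. Question-set labels
inherit the series condition, matching the arithmetic
$78 \times 9 = 702$ with $42 \times 9 = 378$ deceptive-labeled sets.

What the generator does *not* emulate: motion artifacts (excluded, not
corrected, in practice), demographics, countermeasures, habituation across
charts, or between-subject physiological variability beyond amplitude
jitter. Passing tests on this synthetic population therefore demonstrate
that the pipeline recovers a planted relevant-vs-comparison differential
of known size — not field accuracy on human data.

## Numerical choices and degenerate inputs

Zero-variance channels standardize to all-zeros rather than NaN; softmax
logits are max-shifted before exponentiation; cross-entropy clamps
probabilities at $10^{-12}$; 0/0 precision/recall report 0 with a warning;
series with unknown ground truth are scored but excluded from decision
counts; ties at a decision threshold are inconclusive; fold sizes in
stratified k-fold differ by at most one, with class remainders placed on
the currently smallest folds.

## Evaluation harness and problem sizes

`cross_validate()` reports per-fold recall/precision/F1 (deceptive class
positive), their mean ± sd (n − 1 denominator), and a pooled out-of-fold
decision table. The default split unit is the *series*, so all nine
question sets of a series share a fold and no model is ever tested on an
examination it trained on; `unit = "question_set"` mirrors a plain 9:1
split of the pooled sets and is provided because either reading of the
original protocol is defensible.

The package's own validation (test suite) runs the full 10-fold harness on
24 synthetic series at effect size 3 with low noise (`noise_sd` 0.05,
`drift_sd` 0.02), training 2 epochs with batch size 8 and no validation
split — on such strongly separable data the training cross-entropy
collapses below 0.05 within two epochs, so longer schedules add nothing —
and on 12 series at effect size 0 (1 epoch) to confirm the no-signal
chance level. These sizes were chosen once as the smallest populations on
which the 10-fold harness is meaningful.

## Known limitations

* The network's input length (and hence the 22.4 s window) is inferred
  from the published geometry, not documented by its authors.
* The generator's waveform constants are conventions, not measured
  physiology; absolute performance numbers on synthetic data say nothing
  about field accuracy.
* Training is single-threaded CPU code tuned for clarity and
  reproducibility; it is adequate for hundreds of question sets, not for
  large-scale training.
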