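# polycss

Computerized scoring of comparison-question-test (CQT) polygraph charts.

During a CQT polygraph examination, five physiological channels —
photoplethysmogram (PPG), blood pressure, thoracic respiration, abdominal
respiration and skin conductance — are recorded at 40 Hz while the
examinee answers *relevant* questions (about the incident), *comparison*
questions (similar but unrelated controls) and *irrelevant* baseline
questions. The CQT premise: a deceptive examinee responds more strongly to
relevant than to comparison questions; a truthful one does not. Human
examiners score these charts by numerical scoring systems whose judgments
are vulnerable to bias and fatigue; `polycss` is a computerized scoring
system (CSS) that replaces the hand scoring with a deep classifier, for
researchers in psychophysiology and forensic science who want a fully
reproducible, end-to-end scoring pipeline they can train and evaluate on
their own data.

## The method

One **question set** is a (comparison, relevant) question pair. For each
set, a 22.4 s window per channel is cut at each question onset, the two
windows are **offset-joined** (the second is shifted so the junction
samples are equal, removing the boundary discontinuity) and z-standardized
per channel, giving a 5 × 1792 segment. Each channel feeds its own CNN
branch — four valid convolutions (filters and kernels 70/50/30/10, ReLU)
each followed by max-pool 2 and dropout (50/50/25/25 %) — producing the
length chain 1792 → 861 → 406 → 188 → 89. The five 89 × 10 branch outputs
are concatenated into 89 × 50, passed through one 50-unit tanh LSTM
returning all time steps, flattened to 4450 features, and classified by
FC(50, ReLU) → softmax(2). Training minimizes softmax cross-entropy with
Adam (lr 0.0015, batch 64 defaults); the network emits the deception
probability *p* of each question set.

A **series** (three charts × three question sets) receives the score
*s* = Σ₉ *p* ∈ [0, 9]. Decision thresholds map the ±6 cut-offs of the
Utah ±18 numerical scoring scale affinely onto [0, 9]:

    threshold = (cutoff + 18) / 36 × (score_max − score_min) + score_min

giving threshold 1 = 6 and threshold 2 = 3. The decision is **deception**
if *s* > 6, **non-deception** if *s* < 3, **inconclusive** otherwise.

Because real CQT recordings are not public, the package includes a
synthetic session generator (`simulate_dataset()`) that reproduces the
series/chart/question-set structure and plants a controllable
relevant-vs-comparison arousal differential (see the methods vignette,
`vignettes/methods.Rmd`).

## Worked example

Simulate six examination series, train on five, score the held-out one:

```r
library(polycss)

ds   <- simulate_dataset(3, 3, sim_params(effect_size = 3, noise_sd = 0.05,
                                          drift_sd = 0.02), seed = 42)
segs <- build_segments(ds)
segs
#> <css_segments> 54 question sets (5 x 1792 each): 27 truthful, 27 deceptive, 0 unknown; 6 series

fit <- css_fit(segs[which(segs$meta$series_id != "S001")],
               control = train_config(max_epochs = 2, batch_size = 8,
                                      validation_fraction = 0), seed = 1)
fit
#> <css_model> 5-channel CNN -> LSTM -> FC deception classifier
#> <arch_config> 5 branches x 4 conv layers (filters 70/50/30/10, kernels 70/50/30/10), LSTM(50)
#>   shape: 1792 -> 861 -> 406 -> 188 -> 89 time steps -> 89 x 50 -> flatten 4450 -> FC(50) -> softmax(2)
#>   trained 2 epochs on 45 segments (cross-entropy 0.5004 -> 0.0878)

p <- predict_proba(fit, segs[which(segs$meta$series_id == "S001")])
round(p, 3)
#> [1] 0.996 0.989 0.987 0.973 0.994 0.961 0.991 0.944 0.997

score_series(p, series_id = "S001")
#> <series_score> S001 score 8.835 (thresholds 6 / 3): deception
```

The nine probabilities are the per-question-set deception estimates of the
held-out series (truly deceptive here); their sum 8.835 exceeds
threshold 1 = 6, so the series is classified as deception. Ten-fold
cross-validation of the whole pipeline — grouped by series so no model is
tested on an examination it trained on — is one call:
`cross_validate(segs, k = 10, unit = "series", seed = 1)`.

A command-line interface with `simulate`, `preprocess`, `train`, `score`
and `evaluate` subcommands is installed as `exec/polycss`
(see `?polycss_cli`).

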