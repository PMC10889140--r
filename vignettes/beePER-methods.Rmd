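---
title: "Scoring and analysing automated PER conditioning experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analysing automated PER conditioning experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beePER)
```

## The measurement problem

The proboscis extension response (PER) is the standard behavioural readout
of appetitive learning in harnessed honeybees: a bee that has learned that
a conditioned stimulus (CS+) predicts sucrose extends its proboscis to the
CS+ before the reward arrives. Automated rigs replace the human observer
with a camera and a frame classifier, which changes the raw datum from a
binary yes/no per trial to a *probability of extension per frame*. This
package implements the full analysis path from those frames (or
probability traces) to publishable statistics, and a simulator that
generates both frames and whole experiments with known ground truth so
that every stage can be tested end to end.

## Protocol model

An experiment is `n_subjects` bees on a rotor (default 12 positions)
receiving an identical trial sequence. The sequence is balanced (equal
CS+/CS− counts) and starts with an unpaired CS− trial — a contamination
control: naive bees should not respond to an unrewarded cue on trial one.
The remaining trials are a seeded uniform shuffle subject only to exact
count balance; no run-length constraint is imposed. The per-subject
inter-trial interval is `n_positions × cycle_time` (12 × 40 s = 8 min by
default).

Each trial records `trial_duration = 10` s at `frame_rate = 30` fps (300
frames). The CS occupies `[5, 9)` s; on paired (CS+) trials the US starts
1 s before CS offset — the CS–US overlap that drives forward pairing —
and lasts 3 s, outlasting the recording, which scoring simply clamps.
CS/US durations are visible only graphically in typical protocol figures,
so they are configuration keys here (`cs_onset`, `cs_duration`,
`us_duration`, `overlap`) with the defaults above.

## Scoring rules and their numerical conventions

All scoring operates on one convention: frame `i` (1-based) covers
`[(i-1)/f, i/f)`, and a half-open window `[a, b)` contains the frames
whose start time falls inside it.

* **Binarization.** A frame is extended iff `p > threshold` with
  `threshold = 0.8`. The comparison is strict ("a cut *over which* a
  frame counts as extended"); `p = 0.8` exactly is not extended. The
  threshold is configurable.
* **Learning criterion.** A trial is *learned* iff cumulative extended
  time inside the CS-only window — `[cs_onset, us_onset)` on paired
  trials, `[cs_onset, cs_offset)` on unpaired — is at least 0.25 s. "At
  least" rules convert to frame counts as `ceiling(d·f)` (8 frames at 30
  fps, where 0.25 s × 30 = 7.5). The criterion is *cumulative* by
  default because the verbal rule ("extended for a quarter second or
  longer") carries no contiguity qualifier; a contiguous-run mode is
  available via `scoring_params(contiguous = TRUE)` since the choice is
  genuinely underdetermined.
* **Pre-CS exclusion.** A response is discarded when the proboscis was
  already extended for *strictly more than* 0.5 s of the 1 s before CS
  onset (16 frames exclude at 30 fps, 15 do not) — otherwise an extension
  that merely continues into the CS would be scored as learned.
* **Innate-PER filter.** Subjects that fail the pre-training antennal
  sucrose test are excluded wholesale; without the innate reflex the PER
  cannot index learning. The pipeline order is fixed and tested: innate
  filter, then pre-CS exclusion, then the learning criterion.
* **Latency** is the time from CS onset to the first extended frame in
  the CS window; non-responders contribute nothing to mean latencies (no
  imputation).
* **AUC-per-time** is the mean per-frame probability over an analysis
  window, i.e. area under the probability curve divided by its duration,
  a continuous measure that sees sub-threshold responses. For CS+ trials
  the window ends at US onset (extension during sucrose delivery is
  stereotyped and uninformative); for CS− trials the whole trial is
  analysed. The window starts at trial start to match how whole-trial
  averages are usually plotted; `scoring_params(auc_from_cs_onset =
  TRUE)` anchors it at CS onset instead.

The exhaustive oracle test enumerates all 4096 binary traces of a
12-frame trial and checks both duration rules against a brute-force
frame-counting oracle, so the strict/ceiling conventions above are pinned
rather than incidental.

## The frame classifier

No deep-learning framework is available in this package's R dependency
set, so the convolutional network is implemented in the package itself
(RcppArmadillo): im2col 3×3 convolutions with same-padding, ReLU, 2×2 max
pooling, a dense sigmoid head, binary cross-entropy and mini-batch Adam.
Gradients are verified against finite differences in the test suite. The
default architecture uses 8/16/32 channels over three blocks — chosen so
that training on the default synthetic set takes about a minute on one
CPU while still exceeding 0.99 held-out accuracy; `cnn_architecture()`
makes the channel stack, learning rate and batch size pluggable data.

Pixel inputs are grayscale in [0, 1] (color inputs are reduced by taking
the first channel on read). All randomness — weight initialization and
epoch shuffles — is drawn from the R RNG under the caller's seed, so a
fixed `(dataset, epochs, seed)` reproduces the weights bit for bit. The
training metadata records a content fingerprint of the dataset so a
checkpoint can detect fixture drift, plus held-out accuracy measured on a
stratified 20% split never used for fitting. `retrain()` warm-starts from
an existing checkpoint, the workflow used when imaging conditions change:
feed back the misclassified recordings and fine-tune.

## The simulator

The simulator is the package's fixture standard: it generates the
statistical structure the pipeline assumes, with ground truth attached.

Per CS+ trial `k` (the k-th *rewarded* trial) a subject responds with
probability `baseline + (asymptote − baseline)(1 − e^{−k/learn_rate})`;
per CS− trial `k` with probability
`baseline + generalization0 · generalization_decay^{k−1}`. Responding
trials hold probability ≈ 1 from a latency drawn around a mean that
relaxes from `latency0` to `latency_floor` with the same learning rate,
until CS offset (plus the US window on paired trials); non-responding
trials hover near 0. Additive Gaussian jitter (`noise_sd`, clipped to
[0, 1]) models classifier uncertainty. CS− trials may additionally carry
a sub-threshold (peak 0.5) extension "blip" shortly after CS offset —
these exercise the continuous AUC measure without ever flipping a binary
score, mimicking the partial, uncertain extensions that only
probability-resolved scoring can see.

Defaults: `asymptote = 0.85`, `learn_rate = 0.8` (so ~80% of subjects
respond by the third rewarded trial, the acquisition speed typical of
olfactory conditioning), `baseline = 0.05`, `generalization0 = 0.10`
decaying by 0.7 per trial (early generalization that disappears within a
few trials), `latency0 = 1.5` s, `latency_floor = 0.4` s,
`noise_sd = 0.05`. Latency draws are clipped so that a responding trial
always satisfies the 0.25 s criterion: with `noise_sd = 0` the scored
learning curve equals the generative truth exactly, which the tests
assert.

What the simulator does **not** emulate — and what passing tests
therefore cannot certify about real data: spontaneous proboscis
extensions outside the CS (real experiments exclude a small percentage of
responses via the pre-CS rule; simulated traces essentially never trigger
it), photorealistic imagery or antennal motion, satiation and motivation
drift across a session, and between-subject heterogeneity in learning
rate. The synthetic frames are stylized head-on renders (fixed drawing
style, jittered head position, Gaussian pixel noise); they make the
licking/rest classes genuinely but much more cleanly separable than field
video, so the classifier accuracy criterion is a desk-scale analog of a
rig-trained network's training-set accuracy, not a claim about arbitrary
footage.

## Statistics

The response values (AUC-per-time by default) enter a classical
mixed-design (split-plot) ANOVA: stimulus group between units, trial
within units. **Unit convention:** each subject contributes one CS+ and
one CS− series, and the two series are treated as separate independent
units — with `n = 24` subjects the group effect has df `(1, 46)` and the
per-group within effect df `(4, 92)` for 5 trials. This convention is
how df are conventionally reported for this design in the field, and it
is stated prominently because it treats non-independent series as
independent; the sums-of-squares decomposition itself is exact for any
complete design (every unit sees every trial), including unequal group
sizes.

No sphericity correction is applied by default;
`rm_anova(..., sphericity = "GG")` provides Greenhouse–Geisser adjusted
df. Simple between-group effects are computed per trial as a two-group
one-way ANOVA (denominator df `N − 2`); a pooled-error variant (cell-level
error pooled across trials, df `T(N − 2)`) is provided for exploration.
Both variants are labelled with their df; neither is claimed to reproduce
any particular published per-trial denominator, whose pooling scheme is
generally not derivable from the reported design. The per-trial p-value
family is adjusted by the Benjamini–Hochberg step-up procedure (via
`stats::p.adjust`); degenerate trials (zero variance in both groups with
equal means) get `p = 1` by convention, with a message.

The implementation is cross-checked two ways in the tests: against a
naive loop-based sums-of-squares oracle on randomized small tables
(relative error ≤ 1e−8) and against base R's
`aov(y ~ group * trial + Error(unit))` split-plot decomposition; the
type-I error of the group test is verified to sit at the nominal 5% under
a null simulation.

## Problem sizes and runtime choices

The test and acceptance workloads are desk-scale by design: classifier
criteria use 500 frames per class and ~10 training epochs; the oracle
enumeration covers all 4096 12-frame traces; ANOVA calibration uses 2000
null replicates of a 48 × 10 matrix; the end-to-end power check uses 200
replicates of a 24-subject × 10-trial experiment. These sizes make the
full suite run in a few minutes on a single CPU while leaving every
statistical check adequately powered.

## Known limitations

* The classifier is trained and validated on synthetic renders; applying
  it to real recordings requires retraining on labelled frames from the
  actual rig (`retrain()` supports exactly this).
* Frame input is PNG stacks; video containers must be decomposed to
  frames upstream (codec decoding is deliberately outside the package to
  keep the canonical path deterministic).
* The ANOVA requires complete unit × trial matrices; units with excluded
  cells are dropped (with a message) rather than imputed.
* The simulator's acquisition model is the simplest form reproducing the
  canonical qualitative features (exponential acquisition, decaying
  generalization, shrinking latency, sub-threshold offset responses); it
  is a fixture standard, not a fitted behavioural model.
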