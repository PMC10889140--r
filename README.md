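# beePER

Automated scoring and analysis of honeybee proboscis extension response
(PER) conditioning experiments.

In a differential PER conditioning experiment a harnessed honeybee learns
that one cue (the CS+, e.g. an odor or a low air flux) predicts a sucrose
reward (US) while a second cue (the CS−) does not. Modern automated rigs
film each trial and use a frame classifier instead of a human observer:
every video frame gets a probability that the proboscis is extended, and
all behavioural measures are computed from those probability traces.
`beePER` implements everything downstream of the camera for such a rig —
plus a synthetic-data module that stands in for the hardware — for
behavioural neuroscientists who want a tested, reproducible scoring and
statistics pipeline.

## What the package computes

**Frame classification.** A small convolutional network (3×3 conv + ReLU +
2×2 max-pool blocks, sigmoid head, binary cross-entropy, Adam) maps each
100×100 grayscale frame to `P(proboscis extended) ∈ [0, 1]`.

**Trial scoring.** For a trace `p₁ … p_n` at frame rate `f`, a frame is
*extended* iff `p_i > 0.8`. A subject *learned* on a trial iff the
cumulative extended time inside the CS-only window `[t_CS, t_US)` (the
part of the CS not overlapping the US) is ≥ 0.25 s. Responses are
excluded when the proboscis was already extended for > 0.5 s of the
second before CS onset, and subjects without an innate PER to antennal
sucrose are excluded entirely. Latency is the time from CS onset to the
first extended frame; the continuous measure *AUC-per-time* is the mean
of `p_i` over the analysis window (trial start → US onset for CS+ trials,
the whole trial for CS−).

**Statistics.** AUC-per-time values enter a mixed-design repeated-measures
ANOVA with stimulus group (CS+/CS−) as the between-unit factor and trial
as the within-unit factor; each subject contributes one CS+ and one CS−
series treated as separate units (so n subjects give group-effect df
`(1, 2n − 2)`). Simple within-group effects are one-way RM ANOVAs; simple
between-group effects are computed per trial and corrected with the
Benjamini–Hochberg step-up FDR procedure.

**Simulation.** `simulate_experiment()` draws per-trial responses from an
exponential acquisition curve
`P(k) = baseline + (asymptote − baseline)(1 − e^{−k/learn_rate})` for the
k-th rewarded trial, a decaying generalized CS− response, latencies
shrinking with learning, and optional sub-threshold post-CS-offset
extensions; `render_frame()` / `generate_frame_dataset()` draw labelled
synthetic head-on frames for classifier training.

## Worked example

```r
library(beePER)

design <- experiment_design(n_subjects = 24, n_trials = 10, seed = 7)
design
#> PER experiment design
#>   subjects: 24   rotor positions: 12   seed: 7
#>   trials: 10 (5 CS+, 5 CS-), first trial CS_minus
#>   timing: 10 s at 30 fps; CS [5, 9) s; US [8, 11) s on paired trials
#>   sequence: -+-++-+--+

ex     <- simulate_experiment(design, behavior_params(), seed = 8)
scores <- score_experiment(ex)
curve  <- build_learning_curve(scores)
head(as.data.frame(curve), 4)
#>   trial_index condition cs_ordinal n_responding n_eligible   fraction
#> 1           1  CS_minus          1            5         24 0.20833333
#> 2           2   CS_plus          1           14         24 0.58333333
#> 3           3  CS_minus          2            2         24 0.08333333
#> 4           4   CS_plus          2           19         24 0.79166667

fx <- analyze_experiment(scores)
fx$omnibus
#>       effect       F df_num df_den        p
#>   main_group 125.600      1     46 9.63e-15
#>        trial   3.933      4    184 4.35e-03
#>  interaction   4.466      4    184 1.82e-03
```

The learning curve shows the CS+ response fraction rising from 0.58 on
the first rewarded trial towards the simulator's 0.85 asymptote while the
CS− fraction decays to baseline; the ANOVA detects the group difference
(`F(1, 46) = 125.6`) and its growth over trials (the group × trial
interaction, `F(4, 184) = 4.5`). `fx$between` lists the per-trial
contrasts: after BH correction the groups separate from the second trial
on (`p_adjusted = 2.3e-7`) but not on the first, where neither cue has
yet been rewarded.

A subcommand CLI wrapping the same functions ships at
`system.file("cli", "beeper.R", package = "beePER")`
(`sim-frames`, `sim-experiment`, `train`, `classify`, `score`, `analyze`,
`run`).

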