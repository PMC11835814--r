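---
title: "Quantifying branch-point sequence learning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying branch-point sequence learning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchlearn)
```

This vignette documents the statistical procedures implemented in
`branchlearn`, the assumptions behind the closed-loop simulator, and the
design decisions taken where the underlying experimental conventions leave
room for choice. It states no empirical result that the package's tests do
not themselves compute.

## The experimental logic

Songbirds with probabilistic song syntax produce *branch points*: syllables
whose successor is drawn, rendition by rendition, from a stable set of
alternatives. In a sequence-reinforcement protocol, one branch is targeted
with a short white-noise (WN) burst delivered in real time by a template
matcher whenever the bird sings the targeted transition. Birds respond by
reducing the transition probability (TP) to the targeted branch in favor of
the alternatives. Feedback is withheld on a random 10% of renditions
(*catch trials*); these uncontaminated renditions are what learning is
measured on during training days.

A full experiment block per social context consists of one baseline
screening day (BS), 4–5 training days (T1–T5), a post-screen the day after
training (PS1), and further screens roughly one and two weeks later
(PS2, PS3). Contexts — male alone (MA), male–female (MF), male–male (MM) —
are run in a randomized, balanced order within subject.

## Estimators

**Transition tables.** `transition_table()` counts each occurrence of the
branch syllable and its immediate successor. The end of a bout is a real
outcome of a branch point, not missing data, so bout-final renditions are
counted as `END` (this can be disabled with `include_end = FALSE`; it is
never disabled in the pipeline). Probabilities are maximum-likelihood
relative frequencies.

**Degree of learning.** `degree_of_learning(tp_baseline, tp_best)` returns
`100 − tp_best/tp_baseline · 100`. The "best day" of training is not
self-defining; we operationalize it as the training day with the *minimum
catch-trial TP to the target*, with ties broken in favor of the earliest
day (`best_training_day()`). Baseline TP uses *all* BS renditions: no WN
exists during screening, so there is no catch/non-catch distinction and
subsampling would only discard information. The same holds on post-screen
days. On training days the estimate is restricted to catch trials.
A zero baseline TP leaves learning undefined and raises an error rather
than returning an infinity.

**Per-bout transition entropy.** Within one bout, each syllable position
emits one transition (the final position emits `END`). For each syllable
type $b$, $H_b = -\sum_i P(i)\log P(i)$ over its successor distribution,
and the bout's entropy is $TE = \sum_b H_b P(b)$ with $P(b)$ the fraction
of transitions emitted by $b$. The log base defaults to 2 (bits) and is
recorded in every output, since the convention varies across the
literature; base-$e$ values equal base-2 values times $\ln 2$ exactly, and
the tests assert this identity. Entropy is computed on raw syllable
tokens; we do not merge stereotyped chunks into single nodes, so absolute
TE values are comparable only within this convention.

**Song rate and speed.** Song rate is the number of bouts started between
09:30 and 17:00, using the half-open window $[\text{start}, \text{end})$ so
no bout can be double-counted across adjacent windows. Song speed is the
duration of a fixed syllable sequence ("chunk"), onset of first to offset
of last syllable, deliberately including the silent gaps, since both
syllable compression and gap compression contribute to tempo. Chunk
matching is exact-token, leftmost, non-overlapping.

**Early learning.** `binned_learning_curve()` splits the first training
day's bouts into consecutive bins of 50 bouts (configurable) and computes
per-bin TP from all renditions in the bin; the trailing incomplete bin is
reported but flagged. Because song rate differs across contexts, curves
are read at the *last complete bin of the context with the fewest first-day
bouts*, and the same bin index is used for every context
(`last_complete_bin()`). The relative speed of learning is degree of
learning divided by total song rate.

**Targeting accuracy.** Each non-catch rendition is a hit (target sung, WN
delivered), miss (target sung, no WN) or false positive (non-target sung,
WN delivered); accuracy is `hits / (hits + FP + misses) · 100`. Training
days under 75% are excluded from the learning analysis, and every exclusion
is logged by the pipeline.

## Bout segmentation and the mixed-singing exclusion

A bout is a run of one singer's syllables whose silent gaps stay below 2 s.
The comparison is `gap >= threshold` starts a new bout: the convention
"separated by 2 s of silence" does not fix strictness at the boundary, so
we chose the inclusive reading and made the threshold a parameter. A
source-file boundary always ends a bout; files are the recording unit and
nothing guarantees temporal adjacency across them.

In the MM context a file can contain both birds' song. Files with only the
partner's song are dropped. For mixed files, "substantial temporal
overlap" is operationalized as the summed intersection of the two singers'
syllable intervals exceeding a configurable fraction (default 0, i.e. any
measurable overlap) of the subject's total bout duration in that file.
Only the resulting exclusion percentages, not the rule itself, are
conventionally reported, so the rule is a package choice; it is monotone in
the threshold (tested) and auditable from the written exclusion report.
Partner bouts in kept files never contribute to any subject statistic.

## The simulator

The generator is the package's test instrument: it produces complete
experiments with known ground truth, so every estimator can be validated by
parameter recovery. It emulates:

- first-order Markov song from a row-stochastic transition matrix over the
  repertoire plus `END`, with one designated branch point;
- Gaussian syllable and gap durations (truncated at 5 ms), scaled by a
  per-context tempo factor;
- context-dependent song output: dispersed daily bout counts (negative
  binomial, size 20, around the context's mean) and an optional
  entropy factor that interpolates transition rows toward determinism;
- closed-loop feedback: per-rendition catch flags (default 10%), hits at
  `hit_rate` (default 0.93, matching typical template accuracy),
  false positives at 2% on non-target outcomes;
- learning as a multiplicative decrement of the target probability per WN
  experience on the target, `p <- max(floor, p(1-η))`, with the freed mass
  redistributed proportionally over the other outcomes. Within a bout the
  bird sings from the matrix as it stood at bout start; updates take
  effect from the next bout;
- relaxation toward baseline on feedback-free days,
  `p <- p0 − (p0−p)(1−r)^{days}`, so the post-screens show a return to
  baseline over two weeks;
- a fresh learning state at each context block's BS, reflecting the weeks
  in the aviary between blocks.

**Default parameters.** The reinforcement schedule constants are the
protocol's: 10% catch fraction, 40 ms WN, 4 training days, hit rate 0.93.
The learning dynamics are free parameters that the behavioral data cannot
uniquely constrain; we fixed them once at η = 0.05 per experience, floor
0.40 against a baseline target TP of 0.80 (an asymptotic 50% reduction,
inside the 20–80% range typical of reported experiments), and relaxation
0.12/day. The default syntax is deliberately compact — an intro note, one
branch point `x → {a: 0.80, l: 0.19, END: 0.01}`, both branches looping
back — with long bouts (about fifty branch renditions each), as Bengalese
bouts run to hundreds of syllables; long bouts also give the catch-trial
estimators realistic per-day sample sizes. Default context profiles encode
the qualitative pattern of interest: markedly lower song rate (200 vs 140
bouts/day) and slightly faster tempo (2–3%) in the social contexts, with
sequencing entropy left unchanged.

**What the simulator does not emulate.** Acoustics (WN is an event flag,
not a waveform); second-order or history-dependent syntax; repetition
"states" of acoustically identical syllables; female calls or any
interactive social feedback; drift in template accuracy; circadian
structure in song rate beyond a uniform singing window (08:00–18:00).
Passing recovery tests therefore demonstrates correctness of the
estimators under first-order syntax with stationary within-day parameters,
not robustness to these realities.

## Numerical and degenerate-case conventions

- Transition rows must sum to 1 within 1e-9 and remain so after every
  learning update (asserted in tests after long random feedback streams).
- An empty transition table (branch syllable absent) is flagged
  `undefined` rather than fabricating probabilities; catch-only tables
  with no attached feedback log are an error, not silently all-rendition.
- A paired t-test on differences with zero variance is degenerate: an
  exactly zero shift reports t = 0, p = 1; a nonzero constant shift
  reports `NA` with the degenerate flag set.
- The three-way ANOVA fits main effects only; interaction terms would
  exhaust the 18-observation within-subject design. Per-factor F-tests
  are adjusted for the other factors (Type II); on the balanced design the
  error df are $N - 1 - \sum(\text{levels}-1) = 8$. Rank deficiency is
  reported with the aliased terms named.
- The two-proportion test is the continuity-corrected chi-square by
  default, the common default of the analysis environments these
  experiments are processed in; the correction can be disabled.
- Tukey-Kramer is used for post-hoc pairwise comparisons after one-way
  ANOVA.

## Problem sizes used by the test suite

The recovery run simulates the full three-context schedule at 200
bouts/day (about 10,000 branch renditions and 1,000 catch trials per
training day), which makes the catch-trial estimator's sampling error
small enough that a 5-percentage-point recovery band on the degree of
learning is a meaningful check: the dominant error term is the selection
bias of taking the minimum over four near-tied training days, about one
standard error of a per-day estimate. Oracle-equivalence checks run 100
randomized small instances per estimator; null calibration uses 1,000
simulations per test at designs matching the experiment's scale (e.g.
six subjects by three contexts).

## Known limitations

- With the default dynamics the programmed trajectory saturates at the
  floor early on the first training day, so simulated early-learning
  curves are flatter than real ones; slower dynamics can be configured
  where the curve shape itself is under study.
- Transition entropy is computed on raw tokens; merging chunks into
  single syntax nodes would lower bout entropy and is not implemented.
- The pipeline analyzes one subject per run; group-level analyses across
  subjects use the exported inference functions on the per-subject result
  tables.
- The mixed-singing exclusion rule is interval-overlap based; it cannot
  distinguish overlapping song from alternating antiphonal song within
  the same intervals.
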