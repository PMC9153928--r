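---
title: "Dual 2-back trials: task model, simulator, scoring and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual 2-back trials: task model, simulator, scoring and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualnback)
library(dplyr)
```

## The measurement problem

A dual 2-back task presents two simultaneous stimulus streams — a blue
square moving over a 3 x 3 grid (visuospatial) and a spoken digit 0–10
(auditory-verbal) — in trials of 3.330 s, 145 trials per 8-minute block.
The subject presses one key per modality whenever the current stimulus
matches the stimulus two trials earlier in that stream. Performance in each
modality is summarized by seven outcomes: hit rate *H*, false-alarm rate
*F*, the nonparametric sensitivity *A'*, the nonparametric bias *B''*,
working-memory capacity *WM = 2(H − F)*, the mean response latency, and the
latency SD (intrasubject variability). Each is computed for the whole block
and for its two halves; five outcomes additionally get a *delta* (second
half minus first half), and same-name outcomes of the two modalities get a
*discrepancy* (verbal minus visuospatial).

This package implements that whole measurement chain — constrained
sequence generation, a generative cohort simulator, scoring, and the
within-subject inferential battery — as composable tibble-in / tibble-out
functions, so that the full pipeline is reproducible from a seed and every
derived statistic can be recomputed from raw trial logs.

## Sequence generation

A block is laid out in three trial classes:

* **Targets.** Exactly `target_count` trials (default and cap 40, i.e.
  ~28% of eligible trials) are chosen uniformly among trials with at least
  `n_back` predecessors and receive a copy of the stimulus two back.
  Trials 1–2 can never be targets.
* **Lures.** `round(lure_rate * n_trials)` non-target trials (29 of 145 at
  the default rate 0.2) repeat the stimulus at lag `n_back − 1` or
  `n_back + 1` — the standard n-back lure construction, inviting false
  alarms. The lag is chosen at random among the lags that do not
  accidentally complete a 2-back match.
* **Fillers.** Every other trial draws uniformly from the alphabet
  excluding any value that would create an unintended target or lure.
  Sampling directly from the allowed set is distributionally identical to
  rejection sampling until acceptance, and an empty allowed set (possible
  only for tiny alphabets) raises an error naming the trial.

Two numerical choices deserve a note. The lure *rate* is read as a
proportion of all trials, not of non-targets, and is configurable.
Lure *positions* are assigned on the fly with probability
`lures_left / slots_left` per eligible slot, which yields a uniform random
subset of positions; the rare block (~3% of draws) in which a trailing
owed lure cannot be placed without completing a 2-back match is discarded
and redrawn from a derived seed, so the emitted block is a draw conditioned
on satisfying all counts, still a pure function of the seed.

The two modalities of a dual block are drawn from distinct substreams of
one seed and are therefore independent: simultaneous targets in both
streams are allowed and occur at the product of the marginal rates (a
property the test suite checks by Monte Carlo).

## The cohort simulator

The raw data of the motivating study design are not redistributable, so the
package ships a generative stand-in with that design's structure: 31
subjects, five sound conditions (silence, a 240 Hz pure tone, and 10, 16
and 40 Hz binaural beats) administered in an independent uniform random
order per subject, five blocks per session, both modalities scored per
block. All cohort artifacts written by the pipeline are synthetic and
labelled as such by provenance (they are emitted by `simulate_cohort()`).

Responding is Bernoulli on the log-odds scale:

* on target trials, `logit p = logit(hit) + train_hit (block − 1) +
  fatigue_hit [second half] + condition shift`;
* on non-target trials, the analogous false-alarm model plus
  `lure_fa_logodds` on lure trials;
* a responded trial gets a latency `min(3.330, LogNormal(location,
  rt_scale))`, with the location collecting the subject baseline, per-block
  practice, a second-half shift, a centered-age coefficient, a sound-volume
  coefficient and the condition's latency shift.

A logistic-additive response model (rather than an evidence-accumulation
model) was chosen because the scoring stage consumes only response flags
and latencies, and additivity makes every configured effect analytically
checkable: a negative hit-fatigue shift must produce negative scored delta
hit rates in expectation, a condition shift must move exactly its cell, and
a flat profile must recover its generating rates to binomial error. Fatigue
enters as a half-block indicator, not a continuous trend, so the simulator
knob is exactly the contrast the delta outcome measures.

Default calibration (all overridable via `default_population()`): ages
truncated-normal 30.84 ± 6.16 on 19–42 and a 17:14 female:male ratio;
baseline hit/false-alarm logits centered near 0.83/0.07 (visuospatial) and
0.885/0.113 (auditory-verbal) with between-subject SDs of 0.7/0.6 logits;
practice +0.09 logits per block on hits and −0.08 on false alarms; fatigue
−0.40/−0.15 logits on hits and −0.10/+0.25 on false alarms (visuospatial /
auditory-verbal — the false-alarm direction differs by modality on
purpose); latency locations 0.33/0.40 log-seconds with scale 0.32 (block
means near 1.45–1.57 s, within-block SDs near 0.45–0.55 s), practice
−0.028 log-s per block, −0.030 in second halves; age +0.008 log-s per year
and volume −0.02 log-s per SD. Sound volume is a per-subject standardized
constant, as the volume was fixed per participant across conditions.
Because baselines are sampled on the logit scale, realized group-mean
rates sit slightly toward 0.5 relative to `plogis(mean)`; the defaults
keep them inside the plausible ranges above. Condition effects default to
zero — the null configuration — and are the natural knob for power or
recovery experiments.

What the simulator does **not** emulate: feedback-driven within-block
adaptation, response-time/accuracy trade-offs, missed-window or duplicate
keypresses (each trial has at most one response by construction), and any
physiological channel. Passing tests therefore certify the measurement
chain and the statistical machinery, not the behavioral realism of any
particular parameter value.

## Scoring conventions

* **Half split.** By trial index — trials 1–72 versus 73–145 — since trial
  duration is fixed; the odd middle trial goes to the second half.
* **Latency pool.** All responded trials (hits *and* false alarms) enter
  the latency mean and SD by default; `rt_pool = "hits_only"` restricts to
  hits. The default follows from logging responses without restricting to
  targets.
* **Extreme rates.** No loglinear or 1/(2N) correction is applied; *A'* at
  `H = F` is 0.5 by the limit convention (including both rates 0 or 1),
  and *B''* is recorded as missing where its denominator vanishes, which
  is why bias cells can have a reduced n.
* **Ranks.** Midranks with rank 1 = smallest (so rank 5 = largest of the
  five conditions); the Friedman statistic is invariant to the direction,
  which affects only reporting.
* **Linearity.** `WM = 2(H − F)` is linear, so group-mean capacity equals
  twice the difference of group-mean rates — an identity the test suite
  asserts, along with its *failure* for the nonlinear *A'*.

## The inferential battery

* One-sample *t* on each delta against 0, from raw values or from
  `(mean, sd, n)` summaries (identical by construction; `t = mean /
  (sd / sqrt(n))`, df `n − 1`, two-sided). `sd = 0` degenerates to p = 1
  (mean at the null) or p = 0 (off the null).
* Pearson correlations with `t = r sqrt((n−2)/(1−r²))`, df `n − 2`,
  enabling exact recomputation of a p-value from a reported `r` and `n`.
* Friedman's tie-corrected chi-square on the within-subject ranks
  (delegated to `stats::friedman.test`; fully tied rows are the
  chi-square = 0, p = 1 limit).
* Bonferroni pairwise comparisons as paired *t*-tests per condition pair
  with `p_adj = min(1, m p)`, `m = k(k−1)/2 = 10` for five conditions.
  Pairwise error terms (not a pooled error) were chosen: they remain valid
  under sphericity violations, at some cost in power.
* Repeated-measures ANOVA/ANCOVA by the multivariate route
  (`car::Anova`, type III), with Mauchly's test and Greenhouse–Geisser
  correction: both df are multiplied by the epsilon of `gg_epsilon()`
  (always in `[1/(k−1), 1]`), and `p_reported` uses the corrected value
  exactly when Mauchly rejects at 0.05. Numeric covariates are
  mean-centered; unbalanced data belong in the mixed model instead.
* The dual-modality mixed model: fixed effects condition, modality, their
  interaction, plus sex, centered age and volume; a subject random
  intercept; treatment coding with silence and visuospatial as references;
  per-term Wald chi-square tests. Singular fits are flagged, never
  silently dropped. Because the original model selection was manual and
  unreproducible, the package fixes this one canonical term set and
  exposes `fixed =` for deviations — determinism over fidelity to an
  unstated search.
* p-values display as three decimals with `"<0.0005"` below that
  threshold; the band 0.05–0.10 is labelled "marginally significant" as a
  reporting convention only.

## A small worked run

```{r pipeline, eval = FALSE}
log <- simulate_cohort(cohort_design(), seed = 1)
scores <- score_blocks(log)
deltas <- delta_scores(scores)
delta_t_tests(deltas, by = c("condition", "modality", "outcome")) |>
  filter(outcome == "H", modality == "visuospatial")
render_summary(scores, cohort_profiles(log),
               by = "condition", modality = "auditory_verbal")
```

`run_pipeline()` chains the stages and writes every artifact (trial log,
profiles, scores, deltas, discrepancies, ranks, all test tables, summary
tables, config copy and log) to a directory; identical configs produce
byte-identical trees, which the test suite verifies by hashing.

## Problem sizes and numerical checks in the tests

The suite exercises the full 145-trial, 40-target, 29-lure block across
thousands of seeds; parameter recovery uses 500 simulated blocks at fixed
rates (checked to three binomial standard errors); the type-I error of the
delta test uses 10,000 null cohorts of n = 31; oracle equivalence runs 100
random matrices and logs against loop-level brute-force reimplementations;
and the mixed-model checks use 25–60 synthetic subjects, sizes at which
the paired-t equivalence and OLS degeneracies hold to tight numerical
tolerance. These sizes were chosen to bound Monte-Carlo error well below
the assertion tolerances while keeping the default test run fast.

## Limitations

Group-level intervention effects of the motivating design are not
reproducible from summaries, so the package's acceptance surface is the
exactly recomputable layer (derived statistics from printed group means
and summary-to-p transformations) plus the property suites above.
Generative magnitudes are calibration choices, not estimates of any real
cohort's parameters; analyses of real data should treat the simulator
defaults as a null harness, not a prior.
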