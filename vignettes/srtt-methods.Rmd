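---
title: "Analyzing motor sequence learning and consolidation with srttlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing motor sequence learning and consolidation with srttlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srttlearn)
library(data.table)
```

## The task and the measures

srttlearn analyzes keypress-level data from an 8-choice serial reaction time
task (SRTT). Participants respond to a visual cue at one of eight spatial
locations with the corresponding finger. In *sequential* runs the cues cycle
a fixed 8-element sequence (4-7-3-8-6-2-5-1, keys numbered left pinky to
right pinky); in *pseudorandom* runs every 8-trial window contains each
location exactly once with no location repeated on consecutive trials. A
practice block is 48 keypresses — six traversals of the sequence — separated
by 15-s rest intervals.

A single session consists of one familiarization block (not analyzed), four
pseudorandom baseline blocks, sixteen sequential training blocks, four
sequential test blocks, and four pseudorandom control blocks. The
three-session design adds retests approximately 5 h (wake) and 24 h (a night
of sleep) later, each with four sequential and four pseudorandom blocks.
From these the package derives:

- **Trial exclusion.** Within each block, trials with RT beyond `k_sd`
  (default 3) standard deviations from that block's mean are excluded.
- **Baseline normalization.** Each block's mean correct RT and accuracy are
  divided by the participant's mean over the four pre-learning random
  blocks, removing age-related baseline speed differences before
  group comparisons.
- **Learning magnitude** `lm = (R - S)/R`, where `S` is mean normalized RT
  over the sequential test blocks and `R` over the same session's random
  blocks. Positive values index sequence-specific learning.
- **Micro-online / micro-offline gains**: first minus last repetition
  within a training block, and last repetition of block *n* minus first
  repetition of block *n + 1*. The 16 online and 15 offline gains telescope:
  their total equals the first repetition of block 1 minus the last
  repetition of block 16.
- **Macro-offline gains**: mean normalized performance of the session-1
  post-learning test run minus that of the 5 h or 24 h retest run (and
  analogously for the random variant).

### Sign conventions

For an RT outcome, lower is better, and verbal definitions of "difference"
measures are ambiguous about orientation. This package orients **every**
derived measure so that *positive = improvement*: learning magnitude is
`(random - sequential)/random`, and macro-offline gains are *test minus
retest*. This matches the first-minus-last orientation of the micro gains.
Group-difference statistics (F, p, |g|, R-squared) are invariant to this
choice; only the sign of group means and of pairwise mean differences
depends on it, and the documentation states the convention wherever a sign
is reported.

## The synthetic cohort generator

Every stage is tested against simulated cohorts with exported ground truth.
For a participant with baseline RT `B` (ms), the expected log RT of a trial
in cumulative block `t`, sequential block `b`, repetition `r`, after `j`
rest intervals within its run, in session `s`, is

```
log E[RT] = log B
          - general_amp * (1 - exp(-general_rate * t))      # task familiarization
          - seq_amp     * (1 - exp(-seq_rate * b))          # sequence knowledge (sequential runs)
          + within_drift * (r - 1)                          # within-block drift
          - micro_jump   * j                                # rest-interval jumps
          - gain_5h  * [s = 2]  -  gain_24h * [s = 3]       # macro-offline shifts
```

Observed RT is `exp(mu + Normal(0, noise_sd))` — log-normal, because RTs are
positive and right-skewed, which also makes the 3-SD exclusion rule bite the
way it does on real data. With probability `outlier_rate` a trial is
multiplied by a `Uniform(3, 8)` factor, emulating attentional lapses;
responses are correct with probability `acc_p`, errors drawn uniformly from
the other seven keys.

Two indexing choices deserve note, since the cumulative indices are what
make the closed-form oracles exact. `t` counts blocks across the entire
experiment (familiarization = 1), so general familiarization continues into
the retest sessions. `b` counts *sequential* blocks cumulatively across
training, test and retests, so sequence knowledge is carried over sessions
rather than reset — without this, a retest would implausibly restart
sequence learning from zero.

### Default generating parameters

The group-level defaults (`default_group_params()`) are **fabrications**,
chosen once to reproduce the *ordinal* pattern of interest and exposed for
override:

| parameter | CH | AD | YA | OA | rationale |
|---|---|---|---|---|---|
| baseline_rt (ms) | 650 | 480 | 420 | 550 | children and older adults respond more slowly |
| seq_amp | 0.06 | 0.10 | 0.10 | 0.09 | children show less sequence-specific learning |
| micro_jump | 0.012 | 0.008 | 0.008 | 0.008 | children show the largest rest-interval gains |
| gain_5h | 0.05 | 0.04 | 0.00 | 0.00 | children/adolescents improve over the wake interval |
| gain_24h | 0.12 | 0.07 | 0.05 | -0.02 | children largest overnight gains; older adults a small loss |

Shared defaults: `general_amp` 0.12-0.20 (largest in children, who also
learn the task itself), rates 0.15/0.25 per block, `within_drift` 0.004 per
repetition, `acc_p` 0.92-0.96 (accuracy is high and stable by design),
`noise_sd` 0.15 (log scale, a realistic trial-to-trial CV), `outlier_rate`
0.015 with scale (3, 8), which yields cohort trial-exclusion rates between
1% and 3% under the default 3-SD rule. Between-participant SDs are modest
(e.g. 60 ms on baseline, 0.02 on `seq_amp`, 0.04 on the session gains).
There is no quantitative empirical anchor for the within-block dynamics, so
`within_drift` is deliberately small and config-exposed.

Ages are uniform within the group windows (7-12, 13-17, 18-35, 55-75). In
*continuous-age mode* the sequence amplitude becomes a planted quadratic in
age — peak 0.10 at 24 years, curvature -3e-4 per squared year — plus the
usual participant jitter, which exercises the age-trajectory module's
recovery tests with a known vertex.

Each participant receives a child seed drawn deterministically from the
master seed, so cohorts are pure functions of (configuration, seed), and
any participant can be regenerated alone.

### What the generator does not emulate

No drift-diffusion or other mechanistic RT process, no post-error slowing,
no fatigue build-up beyond the linear within-block drift, no explicit
awareness dynamics, and no dependence between micro and macro parameters
(they are drawn independently, so the generator plants no micro-to-macro
correlation). Passing recovery tests therefore demonstrates that the
*pipeline arithmetic and statistics* are correct under a plausible data
model, not that the scientific conclusions transfer to any particular real
dataset.

## Statistical battery

- **One-way and mixed ANOVAs.** The mixed (split-plot) ANOVA uses the
  classical univariate partitioning with a subject random effect. Within
  effects are computed through orthonormal contrasts with sum-to-zero group
  coding, which yields Type-III sums of squares under unbalanced group
  sizes, mirroring common commercial-software conventions. Mauchly's test
  runs on the contrast covariance; Greenhouse-Geisser correction is applied
  when it rejects at `gg_alpha` (default 0.05) and the within factor has
  more than two levels (with two levels sphericity holds identically and
  epsilon is 1). The implementation is cross-checked in the test suite
  against an independent multivariate-model route.
- **Effect sizes.** eta-squared and partial eta-squared with 95% CIs by
  noncentral-F inversion; Hedges' g (bias correction `J = 1 - 3/(4 df - 1)`)
  with CIs by noncentral-t inversion.
- **Pairwise tests.** Tukey(-Kramer) HSD p-values from the studentized
  range distribution using the ANOVA's within-group mean square.
- **Bayes factors.** The t-test BF10 is the exact JZS Bayes factor (Cauchy
  prior, default scale sqrt(2)/2) by adaptive quadrature, cross-checked
  against an independent fixed-grid oracle. ANOVA and regression BFs use
  the BIC approximation `exp((BIC_reduced - BIC_full)/2)` with a subject
  random intercept in both models for repeated-measures designs; these
  match sampling-based defaults at the evidence-category level, not digit
  for digit. Interaction BFs compare the models with and without the
  interaction block.
- **Trend flagging.** Reports mark `0.05 < p < 0.1` as non-significant
  trends.
- **Degrees of freedom.** Conventional dfs are reported throughout
  (between: `N - k`; they are what the F distributions use). Published
  analyses of this design sometimes print dfs inconsistent with their
  stated group sizes; we make no attempt to reproduce such inconsistencies.

## Age trajectories and power

Five candidate forms relate a measure to age: linear, quadratic,
`a x^b`, `a e^(bx)`, and `a e^(bx) + c e^(dx)`. The two sampled age windows
(7-35 and 55-75) are always fitted separately; the gap at 36-54 was never
sampled and a joint fit would interpolate pure fiction. Nonlinear forms are
fitted by profiling the amplitude parameters out exactly (they enter
linearly) and searching the shape parameters from a deterministic grid plus
seeded random multi-starts, then polishing with Levenberg-Marquardt. A form
that fails everywhere is excluded from selection rather than fatal.
`AIC = n log(rss/n) + 2(p + 1)` counts the error variance so rankings are
comparable across forms; fits within ~1e-12 of the total variation are
treated as numerically exact, so on noiseless data ties resolve toward the
more parsimonious form. Only forms with an additive intercept (linear,
quadratic) are invariant to shifting the response by a constant; the power
and exponential forms are not, which is why selection is always re-run per
measure rather than on recentered data.

Power computations use the noncentral F distribution with G*Power
conventions: `lambda = f^2 N` for one-way designs; for repeated measures,
`lambda = f^2 N m / (1 + (m-1) rho)` for between effects and
`lambda = f^2 N m / (1 - rho)` for within and interaction effects. The
package reproduces both canonical design targets of the emulated protocol: a one-way
design with `f = 0.3` reaches 80% power at `N = 128`, and the
group-by-period interaction with `f = 0.2`, `rho = 0.25` reaches 80% at
`N = 108`. Which repeated-measures convention generated a published target
can be ambiguous; the interaction convention is the primary one here, with
the between formula available, and the contractual check is power >= 0.80
at the published N, not the formula's label.

## Numerical and degenerate-input choices

- Exclusion bounds come from all 48 RTs of a block (correct and incorrect)
  in one pass; the rule is idempotent and a zero-SD block excludes nothing.
  Whether published analyses restricted the block mean to correct trials is
  not documented; this choice is recorded and switchable upstream.
- Blocks with no included correct trial yield a *missing* mean RT, never 0;
  missing repetition windows propagate missingness into the micro gains,
  and participants lacking a usable baseline are dropped with a logged
  reason rather than silently.
- The mixed ANOVA refuses incomplete designs and instructs listwise
  deletion upstream, which is what the reporting layer does.
- A worked example:

```{r example, eval = FALSE}
res <- run_pipeline(list(experiment = 2, n_per_group = 27, seed = 1,
                         outdir = "srtt_output"))
res$stats$macro_seq          # group x offline-period mixed ANOVA
res$stats$macro_seq_24h_pairwise
```

## Problem sizes used in the tests

The test suite exercises the pipeline at the emulated protocol's design sizes:
single-session cohorts of 33 participants per group for learning-magnitude
and trajectory checks (99 participants in the 7-35 window), three-session
cohorts of 27 per group (108 participants) for consolidation checks, 500
null-cohort seeds for type-I calibration of the group test, 20 seeds for
macro-gain recovery, and 50 seeds for quadratic-trajectory recovery. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
bands while keeping a full run of the suite in the tens of minutes.

## Known limitations

- The generator's parameters are ordinal fabrications; quantitative
  agreement with any published group mean is not a goal and not asserted.
- The BIC-approximate ANOVA/regression Bayes factors are category-level
  tools; they can disagree with sampling-based defaults by factors large
  enough to matter near category boundaries.
- No linear mixed-effects (REML) machinery beyond the classical mixed-ANOVA
  partitioning is provided, and no multiple-testing correction beyond Tukey.
- The trial schema stores one RT per trial and leaves its semantics on
  error trials (to first keypress vs to correct keypress) to the data
  producer.
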