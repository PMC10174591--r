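---
title: "Models and methods behind fearvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fearvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fearvol` analyses a cue-biased probabilistic reversal-learning task: on
every trial an emotional cue (a fearful or a neutral face) signals which of
four interleaved contingencies is in play, the subject chooses one of two
options, and reward arrives with probability 0.85 for the currently good
option and 0.15 for the other. The good option reverses every 9-11
condition-local trials in the volatile ("freq") conditions and every 18-22
trials in the stable ("infreq") conditions. The scientific question the
toolkit serves is whether fear suppresses the normal adjustment of the
learning rate to environmental volatility, measured by the bias index
$[(\alpha_{fear,freq}-\alpha_{fear,infreq})-(\alpha_{neut,freq}-\alpha_{neut,infreq})]$.

This vignette documents the modelling choices. Every quantitative statement
here is recomputed by the test suite or by `scripts/acceptance.R`; nothing
is quoted from external data.

## Task environment and synthetic cohorts

`task_config()` fixes the design: 60 trials per condition (240 total),
reward probabilities 0.85/0.15, reversal intervals drawn uniformly from
[9, 11] or [18, 22]. Decisions the design leaves open were resolved once:

* the first reversal offset is drawn from the same interval distribution as
  later gaps, and a final partial interval is truncated without a reversal
  (this preserves exact trial counts);
* the initially good option is a fair coin per condition;
* reversal clocks run in condition-local time, since each contingency is
  defined within its own condition;
* non-responses earn nothing and trigger no learning update, but
  forgetting (where a model has it) still decays all values - time passes
  for all four contingencies while any one of them is on screen.

`cohort_spec()` generates synthetic participants. Per-subject parameters
are drawn on the unconstrained (probit) scale around group means and mapped
through the same bound transforms the fitters use. The default preset
encodes the qualitative pattern the pipeline is designed to detect: neutral
learning rates of 0.35 (freq) versus 0.15 (infreq), fearful rates of 0.25
in both volatility levels, inverse temperatures of 3, and a between-subject
sd of 0.5 on the probit scale. These are design parameters of the
generator, chosen once as a realistic effect for this class of task. What
the generator does *not* emulate: response times, sequential response
biases, attention drift within a session, or any coupling between missing
trials and task state - so green tests certify the pipeline's statistical
machinery, not the realism of any particular empirical dataset.

## The model family

Twelve delta-rule learners differ in how parameters are shared across the
four conditions and in which auxiliary mechanism they add (see
`model_spec()`): per-condition learning rates and inverse temperatures
(M1), volatility-only sharing (M2), a shared decision parameter (M3), a
two-armed variant that updates only the chosen option (M4), a lapse mixture
(M5), forgetting decay toward 0.5 - shared, by volatility, or by cue
(M6-M8), Pearce-Hall associability hybrids (M9-M11), and linear links that
express three learning rates as affine functions of the neutral-infrequent
rate (M12). Free-parameter counts are 8, 4, 5, 8, 9, 9, 10, 10, 7, 8, 8,
and 11.

Choices fixed by us where the family's description leaves room:

* values start at 0.5, the indifference level that forgetting decays
  toward;
* the hybrid models put the associability weight and scale in (0, 1), with
  a free initial associability shared across conditions; M10 splits the
  weight and M11 the scale by cue - the only partitions consistent with
  the published parameter counts;
* M12's link outputs are clipped into (1e-6, 1 - 1e-6) instead of
  rejected, keeping the parameter space simple; slopes live in (-2, 2) and
  intercepts in (-1, 1);
* choice probabilities are floored at 1e-12 before logs.

The 240-trial likelihood recursion runs in C++; an independent plain-R
recursion in the test helpers checks it exhaustively on all short
choice/outcome patterns and on randomized longer sessions for all twelve
models.

## Fitting

Bounded parameters are estimated through scaled inverse-probit transforms
(`theta = lower + range * pnorm(x)`), with weakly informative Normal(0, 1)
priors on the unconstrained scale and half-Normal(0, 1) priors on group
scales.

**MAP backend.** `fit_map()` maximises the penalised likelihood with
seeded multi-start BFGS (10 restarts by default) and draws from a Laplace
approximation at the mode; the per-draw pointwise log-likelihoods feed the
information criteria. `fit_cohort_map()` wraps this in a two-pass
empirical-Bayes scheme: the first-pass unconstrained estimates define a
group prior (mean and spread, spread floored at 0.3) under which every
subject is refitted. This partial pooling matters in practice: with 60
trials per condition, small learning rates are weakly identified, and
without pooling they collapse toward the arbitrary prior centre rather
than toward the group.

**Hierarchical backend.** `fit_hierarchical()` samples the non-centered
random-effects model ($x_{sp} = \mu_p + \sigma_p z_{sp}$) with adaptive
Metropolis-within-Gibbs: one block per subject, one per group parameter,
proposal scales tuned toward 30% acceptance during warmup, split-R-hat
reported (a warning, not an error, when above 1.1). Chains can be
warm-started from a `fit_cohort_map()` solution, which shortens warmup
substantially. Point estimates are posterior means. The reference budget
is 4 chains of 4000 iterations; the tests run far smaller chains, which is
enough for point estimation from a warm start but leaves R-hat high -
the diagnostics are reported precisely so that users scale budgets up for
publication-grade inference.

**Model comparison.** WAIC and PSIS-LOO are computed from the pointwise
log-likelihood matrix; the PSIS implementation fits a generalised Pareto
to the upper 20% importance-ratio tail (profile-likelihood estimator)
and replaces tail weights by expected order statistics, reporting the
shape diagnostic. Pseudo-R2 is measured against the chance policy,
$1 - LL/(n \ln 0.5)$, and balanced accuracy averages per-choice-class
one-step-ahead prediction accuracy (probability above 0.5 predicts the
option; exact ties earn half credit). The comparison table reports deltas
relative to the winner (minimum LOOIC; ties broken by WAIC, then by fewer
parameters).

## The volatility observer

A grid filter tracks the tracked option's reward probability $V$, its log
transition width $SV$ (subjective volatility), and a static drift
parameter $k$. Each trial the joint mass is diffused - $SV$ through a
Normal kernel with sd $e^k$, then $V$ through a Beta kernel indexed by the
post-diffusion $SV$ - and reweighted by the Bernoulli likelihood of the
latent outcome of the tracked option (the anticorrelated payoff structure
makes the chosen outcome fully informative; missing trials diffuse without
observing). Default grids: 50 probability bins, 30 $SV$ points on
$[-8, -2]$, 15 $k$ points on $[-6, 1]$, uniform independent priors.

Two choices deserve emphasis because the observer's behaviour depends on
them qualitatively:

* **The width enters as the transition variance.** Parameterising the
  Beta kernel by an inverse concentration instead makes the kernel width
  scale with $V(1-V)$: high-volatility hypotheses then commit *tighter*
  to extreme probabilities, accumulate more evidence than low-volatility
  hypotheses during stable runs, and the inferred volatility ranking of
  fast- versus slow-reversing schedules inverts. With the variance form -
  constrained to unimodal Beta shapes, shrinking the transition mean
  toward 0.5 when the requested variance is infeasible, and limiting to a
  uniform redraw in the wide limit - frequently reversing schedules
  support higher subjective volatility, as they must. The upper grid end
  $SV = -2$ reflects that $e^{SV} > 1/12$ exceeds what a unimodal Beta on
  (0, 1) can express.
* **Resolution independence.** Kernels are built from bin-integrated Beta
  masses with the source value integrated over its bin (3-point
  Gauss-Legendre), and rows whose kernel sd falls below half a bin width
  are replaced by variance-matched tridiagonal kernels. Without these, the
  chain's effective diffusion rate scales with the bin width and the
  filter's output changes visibly when the grid is refined.

## Validation suite and bias statistics

`reversal_curve()` aligns accuracy to reversals (window 9, the minimum
inter-reversal interval, so windows never overlap the next reversal);
`wsls_rate()` counts win-stay/loss-switch transitions between consecutive
valid trials of the same condition, because staying is only meaningful
against the same contingency in an interleaved design;
`third_trial_accuracy()` scores the third trial under each new
contingency. `parameter_recovery()` and `model_recovery()` close the loop
from simulation through refitting; `posterior_predictive()` re-simulates
each subject on their own schedule (100 seeded replicates by default in
place of full posterior draws).

The bias index is tested by a within-subject sign-flip permutation:
swapping cue labels within a subject flips the sign of that subject's
bias, so under the null of no cue-by-volatility interaction the signed
biases are exchangeable and the smoothed two-sided p-value is exact. The
statistic is the (optionally precision-weighted) mean bias;
`cohort_bias_weighted()` builds inverse-variance weights from each
subject's Laplace posterior variance of the bias with a moment-based
between-subject component - the random-effects meta-analytic estimator -
which downweights poorly identified subjects without affecting the test's
validity. Benjamini-Hochberg correction is applied when more than one
covariate is correlated with the bias.

## Problem sizes and numerical conventions

The test suite runs at desk scale by design: recovery and end-to-end
checks use cohorts of 12-40 subjects at the full 240-trial session length,
model recovery uses 10 replicate cohorts against the nested candidate set
{M1, M2, M3, M5}, MCMC checks use 2 chains of a few hundred iterations
from warm starts, and the grid filter's property checks use 50 seeded
sessions. Every stochastic stage takes an explicit integer seed, and the
pipeline fans a single global seed out to stages deterministically, so
identical configurations produce byte-identical outputs.

## Known limitations

* The MAP backend's Laplace draws understate posterior skew for weakly
  identified parameters; the hierarchical backend is the reference
  estimator when budget allows.
* The observer's grid ranges are method parameters; contingencies outside
  roughly 0.05-0.95 reward probability or volatility regimes far outside
  the task's reversal rates would warrant re-choosing them.
* Reaction times, stimulus-level effects and questionnaire scoring are out
  of scope; covariates enter only as per-subject numeric scores.
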