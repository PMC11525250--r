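---
title: "Attention-modulated reinforcement learning models of IED set shifting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-modulated reinforcement learning models of IED set shifting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iedrl)
```

## The task

The CANTAB intra-extra dimensional set-shift task (IED) presents two stimuli
per trial, each composed of at most one feature from each of two dimensions
(lines and shapes). One feature is the hidden target; choosing the stimulus
that contains it yields deterministic positive feedback. Six correct choices
in a row complete a stage; fifty trials without such a run fail the whole
task. The nine stages follow a fixed ladder: simple discrimination and
reversal in the initially relevant dimension (1–2), compound stimuli with the
same target and a compound reversal (3–5), an intradimensional shift to novel
exemplars (6–7), and an extradimensional shift (8–9) in which the previously
irrelevant dimension becomes relevant. `build_task()` constructs this ladder
for either a line-first or a shape-first template; `simulate_participant()`
plays it with any of the three models.

Two modelling conventions are fixed here and matter downstream:

* Stages 3 and 4 are modelled identically. Visually they differ (adjacent vs
  superimposed features), but no quantity in any model depends on that.
* Compound stimuli re-pair the features of the two dimensions uniformly at
  random on every trial, making the dimensions statistically independent.
  The true pairing schedule of the deployed task is not public; independence
  is the neutral choice and is what makes the irrelevant dimension
  uninformative in expectation.

## The models

All three models learn a weight `W(f)` per feature, initialised to 0, and
choose by a softmax on the two stimulus values with inverse temperature
`beta >= 0`.

**fRL** values a stimulus as the sum of its feature weights,
`V = W(f_line) + W(f_shape)`, and after each trial updates every feature of
both stimuli by a delta rule with learning rate `alpha`: the chosen
stimulus's features move toward the feedback `R` (+1 correct, −1 incorrect),
the unchosen stimulus's features toward `−R`. This counterfactual pass
encodes the task's complementarity (exactly one stimulus is correct). Because
fRL treats novel features at stages 6 and 8 identically, its error
distributions on the intra- and extradimensional shifts are
indistinguishable — the property the attention models exist to break.

**Ca-fRL** adds a single attention scalar `theta`, the logit of the attention
paid to the *initially* relevant dimension. Compound stimuli are valued as
`V = sigma(theta) * W(f_rel) + (1 - sigma(theta)) * W(f_irr)`. Learning is a
gradient step on the squared-error loss `L = (target - V)^2 / 2` for each
stimulus in turn (factual pass with target `R`, then counterfactual with
`−R`), so the feature updates are the fRL delta rule scaled by the attention
weight of their dimension, and theta moves by
`alpha * delta * (W_rel - W_irr) * sigma(theta) (1 - sigma(theta))`. Its
starting value `theta0` — dimension primacy — is a free parameter: how
strongly the first-learned dimension dominates when compound stimuli appear.
A large positive `theta0` reproduces the hallmark extradimensional-shift
cost, because stage-8 learning must first drag attention across before the
newly relevant dimension's features can drive choice.

**Sa-fRL** is identical except theta has its own learning rate `eps`,
testing whether feature learning and attention learning are separable
processes. With `eps = alpha` it reproduces Ca-fRL trajectories exactly
(bit-for-bit, which the test suite asserts).

Three further choices were genuinely open and are fixed as follows:

* **Feedback coding.** Targets are `±1`, not `{1, 0}`: symmetric targets keep
  values centred and the softmax shift-invariant. We also evaluated the
  `{1, 0}` coding empirically; it roughly halved every recovery correlation
  and destabilised the hierarchical fit, so `±1` stands.
* **Pass order and theta.** Factual then counterfactual, with theta updated
  in both passes and each pass reading pre-pass weights (one simultaneous
  gradient step, no inner iteration).
* **Single-dimension stages.** Stages 1–2 bypass attention entirely —
  `V = W(f)` and theta is frozen — since dimension primacy is defined by what
  happens when the second dimension first appears at stage 3.

## Parameter transforms and estimation

Learning rates live on `[0, 1]` via the logistic sigmoid, `beta` on
`[0, Inf)` via the exponential, and `theta0` is unbounded; all estimation
happens in the unconstrained space, where the group distribution is modelled
as a diagonal Gaussian. `em_fit()` alternates MAP estimation of every
participant under the current prior (Nelder–Mead from the prior mean plus
perturbed restarts; native `beta` capped at 100 inside the objective to
avoid softmax overflow) with a closed-form M-step: the prior mean is the mean
of the MAPs and the prior variance is the mean of (MAP² + inverse-Hessian
diagonal) minus the squared mean — a Laplace correction that stops the prior
collapsing onto point estimates — floored at 1e−6. Convergence is a maximal
prior change below 1e−3, at most 50 iterations; non-convergence is flagged,
not fatal. The diagonal prior (no covariances) keeps the M-step closed-form
and matches the per-parameter summaries this literature reports.

Numerical choices: per-subject Hessians by central differences (step 1e−3);
non-positive curvature is replaced by the prior precision and flagged;
default five optimisation starts per subject per iteration.

Model evidence is the integrated BIC: each participant's marginal likelihood
is approximated by averaging the choice likelihood over draws from the fitted
prior (default 2,000), and the summed log marginal is penalised by half the
number of prior hyperparameters (two per parameter) times the log of the
total choice count. Less negative is better; exact ties go to the smaller
model.

## The reference regime and what the generator emulates

`reference_prior()` moment-matches the unconstrained Gaussian so that its
*transformed* draws reproduce the native-scale parameter summaries of a
large online general-population cohort (learning rate 0.92 ± 0.14,
determinism 1.34 ± 0.43, primacy 1.78 ± 0.97 for Ca-fRL; 0.62 ± 0.04 and
0.91 ± 0.33 for fRL). The match is closed-form for the log-normal `beta` and
the identity `theta0`, and a two-moment numerical inversion (quadrature plus
Nelder–Mead) for the sigmoid-transformed rates; achieved moments are within
5% and are attached to the returned prior.

`generate_cohort()` produces full synthetic studies: parameters from a
generating prior, sessions via the simulator, and questionnaire totals
(OCI-R, SDRS, STAI-S, STAI-T, SSMS) built by a Gaussian copula on the
standardised unconstrained parameter values. A planted Spearman correlation
`rho_s` is realised through the latent Pearson correlation
`2 sin(pi rho_s / 6)`; totals are scaled to plausible instrument means and
SDs for an unselected online adult sample, rounded, and clipped to the
instrument range (clipping rates are recorded; at the default scales the
realised Spearman stays within ±0.02 of target at n = 10,000, which the test
suite checks). Demographics are age 18–77 (truncated normal, mean 38.8,
SD 13.6), balanced gender, and a six-level education distribution.

What the generator deliberately does *not* emulate: response times, lapses
and attention drift within a session, questionnaire item structure (only
totals are produced), correlations *between* questionnaires beyond those
induced by a shared planted parameter, and any model misspecification —
synthetic participants are exactly the model. Passing tests therefore
demonstrate that the pipeline is correct and well calibrated under its own
assumptions, not that the models are true of human data.

Planted correlations target the *generating* parameter values. Associations
computed on recovered estimates are attenuated by estimation noise roughly in
proportion to the recovery correlation of that parameter, so end-to-end tests
assert sign and significance, never the raw magnitude.

## Validation design

Parameter recovery simulates n participants from the reference prior, refits
them hierarchically, and correlates generating with recovered values per
parameter. Both correlation spaces are reported: the unconstrained space (the
estimation space) and the native space. They disagree most for learning
rates concentrated near 1, where the logit stretches an unidentifiable
ceiling region: many participants solve every stage in a handful of errors
whether `alpha` is 0.95 or 0.999, so unconstrained distances there are
noise. Concretely, for the fRL regime (native SD 0.04) the per-subject
likelihood carries so little learning-rate information that even maximum
likelihood with the true `beta` cannot exceed a recovery correlation of
about 0.25 from a single session — a bound the package's own diagnostics
reproduce — so the learning-rate recovery reported for that model should be
read against this information limit.

Posterior predictive checks simulate (default) ten sessions per participant
at their MAP estimates, pool per-stage error distributions, and correlate
observed with simulated errors on the extradimensional-shift stage within
each replicate, averaging across replicates.

Error-trajectory clustering uses Lloyd's K-means on the raw 9-vector of
per-stage errors (unstandardised Euclidean distance — the trajectory is the
point), ten random-point restarts, best inertia kept; the scree sweep reuses
the best-so-far solution so inertia is monotone in K. Participants who
failed before stage 9 form cluster K+1. The agreement matrix between human
and model-simulated labelings is column-stochastic: each column shows where
one human-defined cluster's simulated data went. Nearest-centroid ties break
to the lowest centroid index.

The association statistics are: Spearman correlations with permutation
p-values (10,000 shuffles without replacement by default, two-tailed via the
absolute coefficient, smoothed as `(b+1)/(n_iter+1)`); Steiger's Z for two
dependent correlations sharing a variable (pooled-r form, one-tailed in the
stated direction — pass absolute values to compare magnitudes); the critical
correlation boundary `t/sqrt(t^2+n-2)`; the Fisher-z minimum detectable
correlation `tanh((z_{1-a/2}+z_{power})/sqrt(n-3))`; plain Bonferroni
division; and OLS with covariates plus group-difference t-tests with
Cohen's d for binary covariates, on complete cases.

## Problem sizes used by the test and acceptance suites

The suites exercise the pipeline at sizes chosen to estimate each property
with comfortable Monte-Carlo margins while staying pleasant to run on a
laptop core: recovery at n = 200 (the stochastic tolerance there is about
±0.07 on a correlation of 0.85); stage-equivalence tests on 2,400 simulated
sessions; model selection over 20 cohorts of 100; permutation calibration
over 50,000 null replicates with 199 shuffles each (the smoothed p-value is
exactly uniform on achievable levels, so 0.05 is attainable exactly);
detection-rate checks over 200 replicates at n = 762. Cohort-scale EM runs
in these batteries use lightened settings (two starts, at most eight
iterations, 500 evidence draws); single-fit analyses use the defaults.

## Known limitations

* The likelihood treats the recorded choices as the complete behavioural
  record; response times and omissions are out of scope.
* The diagonal group prior ignores parameter correlations; if learning rate
  and determinism co-vary in a population, recovery of each is slightly
  conservative.
* The attention layer is indexed to the initially relevant dimension for the
  whole session, so the models cannot represent a second extradimensional
  shift; the task has only one.
* iBIC draws from the fitted prior; with very small cohorts the prior itself
  is noisy and evidence differences below a few units should not be
  interpreted.
* The simulator's agents never fail stages 1–7 in the high-determinism
  regime, whereas a small fraction of humans do; failure-cluster sizes in
  synthetic cohorts are therefore governed almost entirely by dimension
  primacy.
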