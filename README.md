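# iedrl

Trial-by-trial reinforcement-learning models of the CANTAB intra-extra
dimensional set-shift task (IED), for computational psychiatry researchers
who want to go beyond errors-per-stage summaries: a generative task
simulator, three choice models, hierarchical EM parameter estimation with
integrated-BIC model comparison, parameter-recovery and posterior-predictive
validation, error-trajectory clustering, permutation-based symptom
association statistics, and a synthetic-cohort generator so the whole
pipeline runs without access to proprietary task data.

## The models

The IED presents two stimuli per trial, each combining at most one *line*
and one *shape* feature; choosing the stimulus containing the hidden target
feature gives deterministic feedback R ∈ {+1, −1}. Six correct choices in a
row pass a stage; 50 trials without that run fail the task. The target is in
one dimension for stages 1–7 and switches dimension for stages 8–9 (the
extradimensional shift).

All models learn feature weights W(f), start at 0, and choose by softmax
with inverse temperature β:

* **fRL** — feature reinforcement learning:
  V(S) = Σ_{f∈F(S)} W(f), and after each trial
  W(f) ← W(f) + α (target − V(S)) for every feature of each stimulus, with
  target R for the chosen and −R for the unchosen stimulus.
* **Ca-fRL** — adds a dimension-attention logit θ (initial value θ₀, the
  *dimension primacy*): V(S) = σ(θ)·W(f_rel) + (1−σ(θ))·W(f_irr), with
  weights and θ updated by one backpropagation step on the squared-error
  loss per stimulus; a single learning rate α drives both levels.
* **Sa-fRL** — identical, but θ has its own learning rate ε.

Estimation is hierarchical: per-participant MAP estimates under a diagonal
Gaussian group prior in unconstrained space (logit for rates, log for β),
with the prior re-estimated by expectation–maximisation; models are compared
by integrated BIC (marginal likelihood sampled under the fitted prior,
penalised by the number of prior hyperparameters).

## Worked example

Simulate a 40-participant cohort at the package's reference regime, refit it
hierarchically, and inspect the group prior:

```r
library(iedrl)
task <- build_task("line")           # line dimension relevant on stages 1-7
sim  <- simulate_cohort_from_prior("Ca-fRL", reference_prior("Ca-fRL"),
                                   40, task, seed = 1)
fit  <- em_fit(sim$datasets, "Ca-fRL", em_settings(n_starts = 3, seed = 1))
print(fit)
#> Hierarchical fit: Ca-fRL, 40 participants, iBIC -1301.8
#> Group prior (Ca-fRL), unconstrained space:
#>          alpha      beta    theta0
#> mean 2.2569158 0.2848654 2.0855688
#> sd   0.7260333 0.2547909 0.5504928
```

The prior is reported in the estimation (unconstrained) space: the mean
learning rate is σ(2.26) ≈ 0.91, mean determinism exp(0.28) ≈ 1.33, and the
positive dimension-primacy mean (≈ 2.1) says these simulated participants
start compound stages attending mostly to the first-learned dimension —
which is what makes stage 8 hard. A single session and its error trajectory:

```r
ds <- simulate_participant("Ca-fRL",
                           c(alpha = 0.92, beta = 1.34, theta0 = 1.78),
                           task, seed = 7)
print(ds)
#> IED session sim: 90 trials, 9/9 stages completed
errors_per_stage(ds)$errors
#> [1] 3 1 2 0 2 3 1 1 4
```

Power boundaries for a 730-participant correlation analysis:

```r
critical_r(730, 0.05)        # 0.0726 — smallest |r| reaching p < .05
min_detectable_r(730, 0.05)  # 0.133  — smallest r detectable at 95% power
```

A command-line interface wrapping these functions is installed at
`system.file("cli", "iedrl.R", package = "iedrl")` with subcommands
`simulate`, `fit`, `compare`, `recover`, `ppc`, `cluster`, `assoc`, `power`.

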