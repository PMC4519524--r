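---
title: "Model-based and model-free control in the two-step task: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based and model-free control in the two-step task: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepRL)
```

## The task and what it dissociates

The two-step sequential decision task separates two modes of behavioural
control. On each trial the subject makes a first-stage choice between two
stimuli (A/B); that choice leads with fixed probability 0.7 to its "linked"
second-stage state (A→S1, B→S2, a *common* transition) and with probability
0.3 to the other state (a *rare* transition). Each of the four second-stage
stimuli pays a probabilistic outcome — a £1 gain in the reward valence, a £1
loss in the punishment valence — whose probability drifts slowly and
independently between 0.25 and 0.75. Subjects complete 201 trials per
valence, in three sessions of 67.

Because outcome follows the second-stage state, not the first-stage choice
directly, the way an outcome changes the *next* first-stage choice reveals
the controller. A model-free learner repeats first-stage choices that were
followed by a good outcome regardless of how it got there: in the factorial
analysis of stay probability by previous outcome (better/worse) × previous
transition (common/rare), it predicts only a main effect of outcome. A
model-based learner credits the second-stage *state* and plans through the
transition structure, so a good outcome after a rare transition makes it
*switch*: its signature is the outcome × transition interaction. Healthy
adults typically show a mixture of both.

## The generative model

The package's agent is the standard hybrid of SARSA temporal-difference
learning and prospective planning.

**Model-free component.** After each trial,
$\delta_1 = Q_2(s_2, c_2) - Q_1(c_1)$, $Q_1(c_1) \mathrel{+}= \alpha\delta_1$;
$\delta_2 = r - Q_2(s_2, c_2)$, $Q_2(s_2, c_2) \mathrel{+}= \alpha\delta_2$;
and the outcome is carried back to stage 1 with eligibility $\lambda$:
$Q_1(c_1) \mathrel{+}= \alpha\lambda\delta_2$. With $\lambda = 1$ (the fixed
default) these updates collapse to $Q_1(c_1) \mathrel{+}= \alpha(r - Q_1(c_1))$ —
the first-stage value directly credits the final outcome, which is exactly
what makes the pure model-free stay pattern transition-independent.

**Model-based component.** First-stage actions are evaluated through the
known transition structure,
$Q_{MB}(a) = 0.7\,\max_c Q_2(\mathrm{linked}(a), c) + 0.3\,\max_c Q_2(\mathrm{other}, c)$.
Subjects are instructed on the task structure, so no transition learning is
modelled and the true probabilities are used.

**Choice rule.** The two components mix as
$Q_{net} = \omega Q_{MB} + (1-\omega) Q_{MF}$, and first-stage choice is
softmax, $P(a) \propto \exp(\beta Q_{net}(a) + \rho\,[a = \text{previous choice}])$.
The perseveration bonus $\rho$ is omitted at the second stage, and is 0 on
trial 1 and after an omission. Q values start at 0 in both valences, so the
same arithmetic handles gains and losses (the punishment task is the exact
mirror: negating outcomes negates every value).

The four free parameters are the learning rate $\alpha \in [0,1]$, the
inverse temperature $\beta \ge 0$, the perseveration index $\rho$
(unbounded; negative values capture shifting), and the model-based weight
$\omega \in [0,1]$. The baseline Q-SARSA model is the same machine with
$\omega = \rho = 0$ frozen — two free parameters, nested in the hybrid.

Fixing $\lambda = 1$ and sharing one $\beta$ across stages are forced by the
four-parameter count of the winning model; both are conventions of this task
lineage rather than estimable choices here, and both are exposed as
configurable constants (`model_spec()`'s `lam`, bounds).

## Numerical choices

* **Outcome walks.** The per-trial Gaussian step has SD 0.025 (unstated in
  the study description; this is the value of the task lineage the design
  follows) and is *reflected* at 0.25/0.75 rather than truncated, so the
  walk's stationary distribution does not pile up at the bounds. Initial
  probabilities are uniform within the bounds. Walks are regenerated per
  subject by default; `simulate_group_study(shared_schedules = TRUE)`
  freezes one schedule per valence, since the original study does not say
  which was done.
* **Optimisation.** The likelihood is maximised on a transformed space —
  logistic for $\alpha$ and $\omega$, log for $\beta$ (capped at 20 to
  prevent plateau wandering), identity for $\rho$ — by L-BFGS-B from 20
  seeded uniform restarts, with a Nelder-Mead retry for any start that
  fails. Deterministic given the seed.
* **Log evidence.** The per-subject evidence is the BIC surrogate
  $-\mathrm{nll} - \tfrac{k}{2}\ln n_{obs}$ with $n_{obs}$ = 2 × non-omitted
  trials (both stage choices are modelled). The model-selection literature
  for this task uses several approximations (BIC, Laplace); BIC is the
  simplest defensible one and is isolated in `bic_log_evidence()` so a full
  Laplace approximation can be swapped in.
* **Random-effects model selection.** The variational Dirichlet scheme
  iterates subject responsibilities
  $\propto \exp(\text{log-evidence} + \psi(\alpha_m) - \psi(\sum\alpha))$
  and counts $\alpha_m = 1 + \sum_n g_{nm}$ (uniform prior) to a $10^{-8}$
  tolerance; exceedance probabilities use $10^6$ Dirichlet draws.
* **ANOVA.** All within factors have two levels, so sphericity holds
  automatically and no correction is applied. Stay probabilities are
  arcsine-transformed ($\arcsin\sqrt p$) before ANOVA uniformly — the
  original analysis transformed "non-normally distributed" variables, but a
  data-dependent gate would make the pipeline's inferences depend on a
  pre-test; the Shapiro–Wilk screen is still computed and reported where it
  gates the square-root transform of fitted parameters. Subjects with an
  empty factorial cell are excluded listwise and logged. A response with
  zero variance yields F = 0/0, reported as `NA` rather than a number.
* **Seeds.** Every stage seed is derived from one global seed by a Lehmer
  mix kept below $2^{31}$, so studies, fits and Monte-Carlo steps are
  individually reproducible.

## What the synthetic cohorts emulate

The generator mirrors the study design: 22 subjects per group (TD =
tryptophan-depleted, BAL = balanced control — here only labels for the two
simulated cohorts), two valences per subject, 201 trials per valence.
Per-subject parameters are truncated-normal draws around group means.

The study reports no generating parameter values (there are none — the
groups are human). The default scenario therefore states a world consistent
with the study's *findings* and with typical fitted values in this task
lineage: shared means $\alpha = 0.5$, $\beta = 5$, $\rho = 0.5$
(SDs 0.15, 1.5, 0.3), BAL $\omega = 0.45$ (SD 0.12) in both valences, and a
valence-dependent shift for TD: $\omega = 0.08$ (SD 0.08) under reward
(toward model-free control) and $\omega = 0.98$ (SD 0.02) under punishment
(toward model-based control). The shifts must be near-complete: with
$\beta = 5$, a residual weight of even 0.15 on the other controller
produces a detectable factorial effect in a 22-subject group (each residual
effect reaches significance in roughly a third of replicate studies), and
the group then classifies as *mixed*. Near-extreme $\omega$ is what a
clean single-signature read-out at this sample size implies; the values are
stated once here and not tuned per run.

The pure-strategy signature cohorts used for validation set $\rho = 0$ so
that perseveration's asymmetry on the probability scale cannot masquerade
as an outcome effect; the learning signature is then isolated.

Simulated data contain no omissions (the format carries the flag for real
logs), no reaction times, and no session breaks in the learning process —
so green tests establish that the *pipeline* recovers what it should from
data generated by its own model family, not that the model family captures
human behaviour. Parameter recovery draws truths from broad ranges
($\alpha \sim U(0.1, 0.9)$, $\beta \sim U(2, 10)$, $\rho \sim U(-0.5, 1.5)$,
$\omega \sim U(0, 1)$); very low $\beta$ subjects are excluded from that
range because a near-random chooser carries almost no information about
$\omega$ in 402 decisions.

## Known limitations

* BIC log-evidence penalises per-subject; a hierarchical (empirical-Bayes)
  fit would share strength across subjects but the original analysis fits
  each subject separately, and so does the package. The penalty is also
  conservative for weakly identified mixtures: on a single 201-trial
  session, a cohort with mild $\omega$ and moderate $\beta$ can be selected
  as model-free-dominant at the group level even when its factorial
  interaction is clearly present. Decisive hybrid selection needs either
  stronger generating parameters or joint fitting of both sessions.
* The factorial ANOVA treats the arcsine-transformed stay probabilities as
  homoscedastic; cells with few contributing pairs (rare transitions after
  one outcome category) are noisier than common cells.
* `classify_signature()` is a null-hypothesis-test pattern read-out; with
  very large cohorts every tiny effect becomes "significant" and the
  classification saturates to *mixed*. It is meant for study-sized groups.
* Model recovery is demonstrated between Q-SARSA and the hybrid model only;
  intermediate families (e.g. hybrid without perseveration) are expressible
  via `model_spec()`'s frozen values but not part of the default candidate
  set.
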