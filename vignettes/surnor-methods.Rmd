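---
title: "Surprise, novelty and reward: the models behind surnor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprise, novelty and reward: the models behind surnor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surnor)
```

## The task and why it separates novelty from surprise

`surnor` models goal-directed learning in a deterministic environment of 10
states plus an absorbing goal G. States 1–7 form a progressing chain: at
each of them one *good* action moves one step toward the goal (state 7's
good action reaches G), one *neutral* action stays, and two *bad* actions
fall into a set of three trap states (8–10), from which a single *escape*
action returns to state 1. A session has two blocks of five episodes; after
the fifth episode the images displaying states 3 and 7 are silently
swapped, so learned knowledge becomes wrong exactly at those two states
while all other displayed transitions are preserved.

The design decouples three signals that are often conflated:

* **Novelty** is a property of *states*: how rarely a state has been seen,
  regardless of whether it was expected.
* **Surprise** is a property of *transitions*: how strongly an observed
  successor contradicts the learned transition model. After the swap,
  nothing is novel (all images are familiar) but much is surprising.
* **Reward** occurs only at the goal.

Under a uniformly random policy the expected number of actions to reach the
goal, averaged over the ten non-goal start states of the canonical
environment, is above ten thousand (`expected_hitting_time()` solves the
first-passage system exactly), so any realistic behavior must rely on
directed exploration.

The transition table itself is not fully dictated by the published
constraints (which bad action feeds which trap, the traps' internal
wiring). The package therefore ships one fixed *canonical* environment
satisfying every stated constraint — including a shared action label that
leads from both swapped states to the same trap state, so that one action
from each swapped state is unsurprising both before and after the swap —
plus a seeded generator (`build_environment(seed, canonical = FALSE)`) that
randomizes only action labels, never the role structure.

## The learning model

### Novelty (count-based)

Each observed image increments a per-state count $C_s$. The observation
frequency is Laplace-smoothed, $p_N(s) = (C_s + 1)/(t + 11)$, and novelty is
$N(s) = -\log p_N(s)$ (natural logarithm throughout; only orderings and
shapes matter downstream). Counts start at zero, include episode start
states and (by default) goal arrivals, and are never reset — adaptation to
the swap is surprise's job, not novelty's.

### World-model and Bayes-Factor surprise

A pseudo-count table $\tilde C_{s,a \to s'}$ defines the transition model
$p(s'|s,a) = (\tilde C_{s,a\to s'} + \epsilon)/(\tilde C_{s,a} + 11\epsilon)$
with prior weight $\epsilon > 0$. The Bayes-Factor surprise of an observed
transition is the ratio of a *reset* model (uniform, $1/11$) to the current
model, $S_{BF} = (1/11)/p(s'|s,a)$: 1 when the model is still uniform,
large when a confident prediction fails. The adaptation factor
$\gamma = m S_{BF}/(1 + m S_{BF})$ (volatility parameter $m \ge 0$) drives
the variational SMiLe update: the active $(s,a)$ row is scaled by
$1-\gamma$ and the observed successor incremented by one — a plain count
for expected transitions, a reset-and-recount for highly surprising ones.
Only the active row is touched, as the update rule is printed.

### Model-free learner

Two TD channels share one surprise-modulated learning rate
$\rho = \rho_b + \gamma\,\delta\rho$: an external-reward channel (RPE,
discount $\lambda_R$) and a novelty channel (NPE, discount $\lambda_N$)
that treats novelty as an intrinsic reward. Replacing eligibility traces
(decay $\lambda\mu$ per step, reset at episode starts) spread both
prediction errors to recently visited state–action pairs, so a single
novel encounter propagates backward along the path that led to it. The
goal state is terminal in both channels ($V(G) = 0$). $Q_{MF,N}$ starts at
`q_n0` for every pair; $Q_{MF,R}$ starts at zero.

### Model-based planner

A separate pair of Q-tables, $Q_{MB,R}$ and $Q_{MB,N}$, is kept consistent
with the current world-model by prioritized sweeping: a priority queue over
states, seeded at each step with the just-updated state (and, for the
novelty channel, with the just-observed state and its experienced
predecessors, whose planning reward changed), popping up to `t_ps` state
backups per channel per step. Two details matter and were found the hard
way:

* every state starts on the queue, so the initial uniform-model values are
  computed everywhere before experience accrues;
* because the $\epsilon$-smoothed model links every state pair with
  positive probability, value changes propagate priorities through *all*
  potential predecessors, weighted by the strongest transition probability
  into the changed state. Restricting propagation to experienced
  transitions leaves unvisited states stale at their initial values, which
  silently inverts novelty-seeking into familiarity-seeking.

Correctness is defined against an exact value-iteration oracle
(`solve_mb_values()` implements both), not against a particular sweep
schedule; with a generous budget the two agree to $10^{-6}$.

### Hybrid policy

The published description fixes the ingredients of action selection but
not its exact algebraic form, so the package documents its interpretation
explicitly (it uses all 18 free parameters and satisfies every stated
constraint): with block-specific softmax temperature $\beta_b$ and novelty
weight $\beta_N$ ($\beta_{N1}$ in block-1 episode 1, $\beta_{N2}$ in
block-2 episode 1, zero otherwise),

$$U(s,a) = \omega_{scale}\big[\omega_0 Q_{MB,R} + (1{-}\omega_0) Q_{MF,R}
 + \beta_N(\omega_{1b} Q_{MB,N} + (1{-}\omega_{1b}) Q_{MF,N})\big],$$

$$\pi(a|s) \propto \exp(\beta_b\, U(s,a)),$$

with $\omega_{11}, \omega_{12}$ the block-specific model-based shares of
the novelty mix. Ties in any argmax are broken toward the lowest index
(a measure-zero concern).

### The competitor roster

Thirteen models are shipped: the full model (`SurNoR`), a random-choice
null (`RC`), and eleven alternatives crossing policy (pure model-based,
pure model-free, hybrid) with exploration strategy (novelty-seeking `+N`,
optimistic initialization `+OI`, surprisal/uncertainty-seeking `+U`) and
surprise modulation (`+S`; models without it use a constant pseudo-count
leak `gamma_leak` and the constant learning rate $\rho_b$). Model-free
variants still maintain a world-model where surprise is needed, but never
consult it for action planning. Two Binary-Novelty controls replace the
graded novelty signal by a fixed reward of $-1$ for over-visited states
(count threshold, or membership in the top-*n* most visited); fixing the
reward magnitude (it is absorbed by the $\beta_N$ weights) leaves each
control with exactly 19 free parameters, against 18 for the full model and
0 for `RC`.

## Default parameters

The study's fitted parameter values are not recoverable from the published
text (they live in an undeposited spreadsheet), so the package's defaults
were calibrated once against the quantitative facts the text does print,
and then frozen:

* baseline model-free learning rate $\rho_b = 0.06$, with
  $\delta\rho = 0.5$ so the saturating-surprise rate is 9.3 times the
  baseline (the text reports 0.06 and a ratio above 8);
* a 200-agent simulated cohort yields a discarded fraction of 0.29 ± 0.03
  under the 500-action quit filter (reported: 31 ± 3%);
* on the agents that pass the filter, the first episode after the swap is
  shorter on average than the very first episode, later episodes collapse
  to a few actions, trap-escape latency declines with trap visits, and
  progress at unchanged states survives the swap.

Two scale facts shaped the calibration. Reward-channel Q-values live on a
$\le 1$ scale and their differences at chain-distal states are a few
hundredths, so sharp exploitation requires large softmax temperatures
($\beta_1 = 25$, $\beta_2 = 60$) and correspondingly small novelty weights
($\beta_{N1} = 0.003$, $\beta_{N2} = 0.01$). And `q_n0 = 24`
($\approx \log 11/(1-\lambda_N)$, the value of an endlessly novel stream)
keeps untried actions attractive in the novelty channel — the optimism
that lets agents break out of post-swap habit loops. Remaining defaults:
$\epsilon = 0.01$, $m = 0.2$, `t_ps = 30`, $\lambda_R = 0.95$,
$\lambda_N = 0.9$, $\mu_R = \mu_N = 0.8$, $\omega_0 = 0.8$,
$\omega_{11} = 0.75$, $\omega_{12} = 0.25$, $\omega_{scale} = 1$.
($\omega_0 = 0.8$ gives the *raw* model-based weight; the effective-weight
analysis of `branch_dominance()` still finds the model-free branch
dominant, because model-free Q-value spreads are much larger.)

Block-2 start states are not published; the package reuses the block-1
sequence 6, 9, 4, 5, 8 (configurable), an assumption flagged here.

## Fitting and model selection

`surnor_fit()` maximizes the exact action-sequence log-likelihood by
coordinate ascent with per-coordinate grid search, repeated from random
grid initializations (convergence: absolute improvement below $10^{-6}$
over a full sweep; ties toward the first grid point). Grid bounds and
spacings are package defaults (`surnor_grids()`), overridable; a
single-value grid pins a parameter.

`crossval_evidence()` treats the cross-validated held-out log-likelihood
as model evidence: participants are split into three fixed folds (of four,
at the study's cohort size), each participant is scored under parameters
fitted to the other folds, and the whole process can be repeated with
re-randomized restarts to quantify optimizer noise (fold assignment stays
fixed — re-randomizing restarts only is the package's reading of the
repetition procedure). `bms_random_effects()` then runs random-effects
Bayesian model selection: variational estimation of a Dirichlet posterior
over population model frequencies (prior concentration $1/K$), exceedance
probabilities by Monte-Carlo sampling of that posterior, and protected
exceedance probabilities through the Bayesian omnibus risk.

Accuracy uses the fractional tie convention (a trial counts $1/n$ when the
taken action ties with $n-1$ others at maximal probability), which makes
the random-choice baseline exactly 25%; uncertainty is the mean Shannon
entropy of the policy (random choice: $\log 4$).

## Synthetic cohorts and recovery analyses

`simulate_cohort()` generates fully synthetic participants with the
study's session structure; these simulations are the package's stand-in
for the human data, which are not deposited. Consequently the
human-derived numbers (log-evidence tables, accuracy percentages on real
participants) are not reproduction targets; what the test suite verifies
is the self-contained quantities (environment analytics, exact
random-choice metrics, equation-level identities, the quit-filter
fraction, the learning-rate ratio) plus *recovery*: on cohorts generated
by the full model, coordinate-ascent fitting recovers parameters whose
implied trial-by-trial model variables correlate strongly with the
generating ones, and cross-validated evidence plus random-effects
selection recover the generating model against its strongest competitors
(`MF+S+N`, `Hyb+S+U`, `Hyb+N`, `RC`).

The recovery analyses in the test suite run at deliberately reduced size —
12-agent cohorts, one to two optimizer restarts, and a restricted
coordinate set over the coarse grids (temperatures, novelty weights,
volatility or leak, learning rate, model-based weight; the remaining
parameters stay at their defaults). These sizes are the package's choice
of a minimal convincing recovery demonstration; the same functions scale
to the study's 25 restarts and full grids by changing arguments.

What the synthetic cohorts do *not* emulate: reaction times, lapses and
attention drift, between-participant parameter heterogeneity (all agents
share one parameter set; variability is purely from action sampling), and
participants' prior knowledge of images. Passing recovery tests therefore
demonstrates internal consistency of the pipeline, not validity on human
data.

## ERP regression

The encoding analysis takes per-trial model variables (Surprise, Novelty,
NPE, RPE, Reward) extracted from a fitted agent and relates them to
trial × time-point ERP matrices (65 points, −100 to 650 ms):

* `build_regressors()` normalizes the five variables, replaces the
  strongly correlated Reward/RPE pair by their principal components
  $R_+ = $ Reward + RPE and $R_- = $ Reward − RPE, and orthogonalizes the
  other three to both (renormalizing afterwards);
* `encode_mlr()` fits per-time-point OLS and reports adjusted $R^2$
  (negative under the null is expected);
* `window_stats()` runs one-sample t-tests across participants per
  post-onset time point under Benjamini–Hochberg FDR control at 0.1,
  groups contiguous significant points into windows, splits windows longer
  than 8 points (≈ 95 ms) into two equal halves, and t-tests time-averaged
  coefficients per window with per-window FDR;
* `grand_correlation()` pools all participants' trials after dividing each
  participant's ERPs by their RMS amplitude — the package's reading of
  "normalizing by the overall squared energy", chosen because it actually
  equalizes second moments and makes the result invariant to
  per-participant rescaling — and computes per-time-point correlations
  with Fisher-z 95% confidence intervals; RPE analyses exclude block-1
  episode-1 trials (where RPE carries no signal).

Because no ERP data ship with the package, `synth_erp()` plants a known
coefficient-by-time profile (by default a positive peak near 300 ms for
Surprise, Novelty, NPE and $R_+$, mimicking the classic P300 association)
with Gaussian noise; the test suite verifies the full round trip from
planted profile to recovered significant window.

## Numerical and engineering choices

* The agent loop exists twice by design: a plain-R reference built from
  the exported primitive operations (`agent_step()`, the file
  `R/agent.R`), and a compiled core (Rcpp) used by simulation and
  likelihood fitting. A parity test holds the two to identical outputs on
  replayed trajectories; the update order per step is fixed and
  documented: novelty reward from pre-update counts, surprise from the
  pre-update world-model, SMiLe update, count recording, model-free
  updates, model-based sweeps, action choice at the new state.
* Prioritized-sweeping tolerance $10^{-9}$; predecessor seeding for the
  novelty channel uses experienced transitions (pseudo-count $> 0.01$).
* Monte-Carlo sizes: exceedance probabilities default to $10^6$ Dirichlet
  draws (tests use $10^5$); the hitting-time cross-check uses $10^3$
  episodes per start state.
* All randomness flows from a single master seed through
  `seed_sequence()` (per-agent, per-restart, per-draw children), so every
  analysis is reproducible from one integer.

## Known limitations

* The hybrid-policy algebra and the prioritized-sweeping variant are
  interpretations of a description whose exact form is in unpublished
  supplementary material; both are documented above and isolated behind
  small functions.
* Episode truncation (the step cap) is an artifact of simulation; capped
  episodes are flagged and excluded from behavioral summaries by default.
* The coordinate-ascent optimizer is a grid method: parameters between
  grid points are unreachable, which is visible in recovery as
  quantization of the recovered values (the model-variable correlations
  are the meaningful recovery metric, as in the study's own robustness
  analysis).
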