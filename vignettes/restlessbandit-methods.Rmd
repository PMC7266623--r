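---
title: "Modelling explore/exploit behaviour in a restless four-armed bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling explore/exploit behaviour in a restless four-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(restlessbandit)
library(dplyr)
```

## The task and its generative model

In a restless four-armed bandit task, a player repeatedly (300 trials, in
four blocks of 75) picks one of four options whose mean payoffs drift over
time, earning points that convert to money at 5 cents per 100 points.
Because the payoffs drift, the value estimates of unchosen options become
stale and uncertain, so a good player must keep balancing *exploitation* of
the currently best option against *exploration* of options whose value is
uncertain.

Each bandit's latent mean payoff follows a decaying Gaussian random walk

$$\mu_{i,t+1} = \lambda\,\mu_{i,t} + (1-\lambda)\,\vartheta + v_t,
\qquad v_t \sim N(0, \sigma_d^2),$$

with decay $\lambda = 0.9836$, decay center $\vartheta = 50$ points and
diffusion sd $\sigma_d = 2.8$; the realized payoff adds observation noise
with sd $\sigma_o = 4$ and is rounded to non-negative integer points
(points are displayed as integers in the task; latent means stay
continuous). The latent process is an AR(1) with stationary mean
$\vartheta$ and stationary sd
$\sigma_d / \sqrt{1-\lambda^2} \approx 15.5$ points, which keeps walks
mostly inside the 0-100 display range without clipping — clipping would
distort the generative model, so we do not do it.

```{r walk}
walk <- generate_walk(seed = 1)
walk |> filter(trial <= 3)
stationary_sd(walk_params())
```

Choices about initial conditions and randomness:

* **Initial latent means** are drawn uniformly within two stationary sds of
  the center. The original task reused three fixed walk instantiations whose
  values are not published, so walks are regenerated; their identity is
  irrecoverable and nothing downstream depends on it.
* **RNG contract**: every generator takes one seed from which independent
  sub-streams are derived — one per bandit for the walk, separate streams
  for parameter draws and choices. Bandits are therefore exchangeable:
  permuting the per-bandit streams permutes walk columns exactly.
* **Payout rounding** is half-up to whole cents.

## Learning models

Two learning rules map reward history to per-bandit beliefs.

**Bayesian learner (Kalman filter).** The belief about bandit $i$ before the
choice on trial $t$ is Gaussian with mean $\hat\mu^{pre}_{i,t}$ and variance
$\hat\sigma^{2,pre}_{i,t}$. Observing reward $r_t$ for the chosen bandit $c_t$
gives the conjugate update

$$\hat\mu^{post}_{c_t} = \hat\mu^{pre}_{c_t} + \kappa_t \delta_t,\quad
\delta_t = r_t - \hat\mu^{pre}_{c_t},\quad
\hat\sigma^{2,post}_{c_t} = (1-\kappa_t)\,\hat\sigma^{2,pre}_{c_t},\quad
\kappa_t = \frac{\hat\sigma^{2,pre}_{c_t}}
               {\hat\sigma^{2,pre}_{c_t} + \hat\sigma_o^2}.$$

Unchosen bandits keep their priors within the trial. Between trials all four
beliefs drift according to the learner's model of the walk:

$$\hat\mu^{pre}_{i,t+1} = \hat\lambda\,\hat\mu^{post}_{i,t}
  + (1-\hat\lambda)\,\hat\vartheta, \qquad
\hat\sigma^{2,pre}_{i,t+1} = \hat\lambda^2\,\hat\sigma^{2,post}_{i,t}
  + \hat\sigma_d^2.$$

So the uncertainty of an unchosen bandit grows toward the stationary value
while repeated sampling drives the chosen bandit's uncertainty to a lower
fixed point — the engine behind directed exploration.

**Delta rule.** Values update with a constant learning rate,
$v_{c_t} \leftarrow v_{c_t} + \alpha\,\delta_t$, and do not decay between
trials. Because choice rules 2-4 need a per-bandit uncertainty for the
exploration bonus and the Kalman *variance* recursion is independent of the
observed rewards (it depends only on which bandit was chosen), the Delta
learner carries that same variance recursion for its $\sigma^{pre}$ term
while updating values with $\alpha$. This is the only construction under
which the published free-parameter lists of all eight models are coherent;
it nests the Bayesian learner's uncertainty dynamics while isolating the
learning-rule difference to the means.

Fixed learner parameters default to the true generative values
($\hat\lambda = 0.9836$, $\hat\vartheta = 50$, $\hat\sigma_o^2 = 16$,
$\hat\sigma_d^2 = 7.84$), and the initial prior is $N(50, 15.5^2)$ (the
stationary sd) with Delta values starting at $v_1 = 50$. Treating the
initial prior as fixed rather than free matches the published parameter
table and stabilizes hierarchical fits; `learner_params()` exposes all of
them for users who want different fixed values. Estimating the initial
prior as free parameters is deliberately not offered: it destabilizes short
hierarchical fits for no benefit on 300-trial sessions, where the initial
prior's influence washes out within a few trials.

**Missed trials** (no response within the deadline) get no within-trial
update and contribute nothing to the likelihood, but between-trial drift
still applies. A missed trial also clears the previous-choice marker, so the
following trial carries no perseveration bonus — the bonus is defined for
"the bandit chosen on the previous trial", and on a missed trial none was.

## Choice rules

All four rules are softmax policies over an augmented value, with the
inverse temperature multiplying the full bracket:

1. **SM**: $P_{i,t} \propto \exp(\beta\,\hat\mu^{pre}_{i,t})$ — random
   exploration only.
2. **SME**: adds the directed-exploration bonus,
   $\beta[\hat\mu^{pre} + \varphi\,\hat\sigma^{pre}]$.
3. **SMEP**: adds a constant perseveration bonus $\rho$ for the bandit
   chosen on the previous trial.
4. **SMERP**: adds a total-uncertainty random-exploration term
   $\gamma\,\hat\mu^{pre}_i / \Sigma\sigma^{pre}$, where
   $\Sigma\sigma^{pre}$ sums the prior sds of all four bandits.

The printed form of rule 2 has a bracket ambiguity; rule 3 shows $\beta$
multiplying the full augmented value unambiguously, and we apply that
convention uniformly so the rules nest exactly under parameter zeroing
(`choice_prob_smerp(..., gamma = 0)` is identical to `choice_prob_smep(...)`
and so on). The bonus uses the pre-choice (post-drift) prior sd, the same
convention as the value term. On each session's first trial there is no
previous choice and no perseveration bonus. Probabilities are computed with
log-sum-exp stabilization everywhere; inside the likelihood (only) they are
floored at machine epsilon so that degenerate parameter proposals yield a
finite, strongly penalized log-likelihood instead of `-Inf`.

Two learning rules crossed with four choice rules give the eight-model
space:

```{r registry}
model_registry()
```

## Synthetic cohorts

`simulate_cohort()` emulates the study design: 31 subjects, three
within-subject conditions (`placebo`, `ldopa`, `haloperidol`), 300 trials
per session, one independent payoff walk per condition shared by all
subjects (as with the task's fixed instantiations). Subject-level
parameters are drawn from condition-specific group normals
$N(M_x, \Lambda_x)$, truncated to each parameter's support: $\beta \ge 0$
and $\alpha \in [0,1]$; $\varphi$, $\rho$, $\gamma$ are left signed because
the scientific question is precisely whether $\varphi$ is attenuated, which
presumes signed support.

The default ground truth is $M_\beta = 0.29$, $M_\varphi = 1.34$,
$M_\rho = 4.11$ with $\Lambda = (0.1, 0.5, 1.5)$. The means repurpose one
representative subject's published posterior medians as plausible values;
the spreads are our choice of a realistic between-subject heterogeneity
(the fitted group estimates are shown only graphically in the source study
and cannot be read off). They are synthetic stand-ins, documented as such,
and every test that uses them treats them as the known ground truth of a
simulation, never as estimates of the real cohort.

`emulate_study_effect()` reduces $M_\varphi$ in the `ldopa` condition only
(default 50%), mimicking the reported dopaminergic attenuation of directed
exploration; response omissions can be simulated at a configurable rate
(default 0, since the real design's omission rate is not reported).

## Hierarchical Bayesian estimation

Each condition is fitted as an independent hierarchical model, matching the
study's per-condition estimation: uniform priors on the group means
(defaults $\alpha \in [0,1]$, $\beta \in [0,3]$, $\varphi \in [-10,10]$,
$\rho \in [-15,15]$, $\gamma \in [-10,10]$ — the published scheme's limits
are not printed, so these are chosen wide enough to cover all plausible
values and are configurable), half-Cauchy(0, 1) priors on the group sds, and
truncated-normal subject-level priors.

No Hamiltonian Monte Carlo backend is available in this environment, so the
sampler is a hand-written **adaptive Metropolis-within-Gibbs**: scalar
random-walk proposals for every subject-level parameter (one data
log-likelihood evaluation each, computed in C++), and Metropolis updates for
each group mean and (log-)sd. Group-level updates touch no data likelihood,
so they are swept ten times per iteration to decorrelate $(M, \Lambda)$ from
the subject draws. Proposal scales adapt toward 44% acceptance in batches of
25 during warmup only (diminishing adaptation), which preserves the correct
stationary distribution afterwards. Chains are initialized from per-subject
penalized maximum-likelihood estimates (`fit_subject_map()`) with jitter;
with short chains this matters more than overdispersed inits, and
convergence is still verified rather than assumed: split-R-hat and a bulk
effective sample size are computed for every group-level parameter, a fit
whose worst R-hat exceeds 1.1 warns and carries `converged = FALSE`, and
divergence counts are reported as `NA` (they are an HMC-specific
diagnostic).

The default sampling contract mirrors the study (4 chains, 1000 warmup and
1000 retained iterations, no thinning); `ci_profile()` is the reduced
profile used by the test suite (2 chains, 250/250, 8 subjects), which the
parameter-recovery test shows is already sufficient for subject-level
true-vs-recovered correlations above 0.7 for $\beta$, $\varphi$ and $\rho$.

Drug-effect style contrasts use the 90% highest density interval of the
draw-wise difference of group means between two independently fitted
conditions (`condition_contrast_hdi()`); the HDI is the shortest
sorted-sample window, validated against a brute-force search in the tests.

## Model comparison

Predictive accuracy is estimated by PSIS-LOO with one held-out unit being
*one subject under one condition compounded over trials*, exactly the
study's cross-validation unit — not per-trial, which would leak sequential
information (a per-trial variant is deliberately not offered as a headline
number). Pointwise log-likelihoods are stored at every retained draw of the
subject-level parameters. The Pareto-smoothed importance sampling follows
the standard recipe: the largest 20% of importance ratios are replaced by
quantiles of a generalized Pareto distribution fitted by the Zhang-Stephens
posterior-mean method, capped at the largest raw ratio, with units flagged
when the tail shape exceeds 0.7. Because no LOO package is available in
this environment, the implementation is ours and is validated against an
exact conjugate-Gaussian leave-one-out oracle in the tests (agreement well
within 0.5 elpd per unit at the standard reliability threshold).

Comparison tables report the total and the normalized LOO (per data point,
as in the study's figure; the division is a linear rescaling and cannot
change the ranking) plus pairwise differences to the best model with
standard errors from per-unit contributions.

## Trial classification and regressors

A trial is an **exploitation** when the chosen bandit is in the argmax set
of the prior means; ties count as exploitation (they arise at trial 1 where
all beliefs are equal, and are measure-zero afterwards). Exploration trials
split into **directed** (chosen bandit has the highest prior sd among all
four bandits) and **random** (any other). Exploitation takes precedence: a
bandit that is both max-value and max-uncertainty counts as exploitation,
since directed/random are defined only within exploration trials. Whether
the original analysis took the uncertainty argmax over all bandits or only
over non-best bandits is not stated; the all-bandits reading with
exploitation precedence is adopted and flagged here. Missed trials are
excluded from all percentage denominators.

`compute_regressors()` exports the trial-wise quantities used as
neuroimaging regressors — $\hat\mu^{pre}$ and $\hat\sigma^{pre}$ of the
chosen bandit, prediction error $\delta$, choice probability, total
uncertainty $\Sigma\sigma^{pre}$, perseveration indicator and trial class.
$\Sigma\sigma^{pre}$ rises steadily during a run of exploitations and drops
abruptly after an uncertain bandit is explored; the test suite asserts this
on constructed sequences.

```{r classify}
spec <- cohort_spec(n_subjects = 2, conditions = "placebo", seed = 8)
d <- simulate_cohort(spec)
regs <- compute_regressors(d, "bayes_smep", attr(d, "true_params"))
behavioral_summary(regs)$overall
```

## What the generator does and does not establish

The synthetic cohort reproduces the study's *structure* (within-subject
design, session length, payoff process, hierarchical parameter
heterogeneity, a condition-specific reduction of $M_\varphi$) with known
ground truth, so green tests establish that the estimation and
classification machinery recovers what it should from data of this shape
and size. It does not reproduce reaction times, drug pharmacokinetics,
session order effects, learning across sessions, or any feature of the real
participants' deviations from the fitted model family; no number computed
here estimates the real cohort's parameter values.

## Numerical choices and limitations

* Walk noise sds of exactly zero are admitted by `walk_params()` so the
  decay recursion itself can be probed; the generative defaults are
  strictly positive.
* The exact-equality tolerance for argmax ties in classification is 1e-12.
* `fit_subject_map()` adds a weak $N(0, 10^2)$ ridge to keep optimizations
  away from likelihood plateaus; it is a smoke-test and initialization tool,
  never the basis of headline contrasts.
* Metropolis-within-Gibbs mixes more slowly than HMC; the reduced test
  profile is calibrated for the 8-subject synthetic cohorts used in CI, and
  study-scale fits should use the default 4 x 1000/1000 profile and check
  `glance()` diagnostics.
* LOO standard errors assume approximately independent unit contributions
  (93 units at study scale); with few units (toy fits) they are indicative
  only.
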