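---
title: "Modular reinforcement learning and sparse modular IRL for naturalistic navigation"
author: "modirl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular reinforcement learning and sparse modular IRL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decision model

`modirl` models multi-task navigation — walking a curved path across a
room while collecting targets and avoiding obstacles — as a *modular*
Markov decision process.  Each behavioral subtask (module) is its own
small MDP with a private scalar reward $r^{(n)}$ and discount factor
$\gamma^{(n)}$, sharing one action set: $K = 16$ headings in $22.5°$
bins, each action a step of one grid cell (default $0.572$ m, about a
stride) in a continuous $8.5 \times 7.3$ m room.  Under deterministic
dynamics, and assuming a module policy that heads straight for its
object, a module object's action value has the closed potential-field
form

$$Q^{(n)}(s^{(n,m)}, a) = r^{(n)} \, \bigl(\gamma^{(n)}\bigr)^{d(s^{(n,m)},\,a)},$$

where $d$ is the distance, in step units, from the agent's post-action
position to object $m$ of module $n$.  The global action value sums
these over all modules and all of their live objects, and action choice
is Boltzmann (softmax) with confidence $\eta$:

$$Q(s,a) = \sum_n \sum_m Q^{(n)}(s^{(n,m)}, a), \qquad
P(a \mid s) \propto \exp\{\eta\, Q(s, a)\}.$$

Objects disappear on contact, so the composed value surface deforms as
the trial unfolds; the trial ends when the goal at the end of the
waypoint path is consumed.

## The estimator

Given observed (state, action) sequences, sparse modular IRL maximizes
the trajectory log-likelihood with an $L_1$ penalty on module rewards,

$$\max_{r^{(1:N)},\,\gamma^{(1:N)}} \;\sum_t \Bigl[\eta\, Q(s_t, a_t)
  - \log \textstyle\sum_a e^{\eta Q(s_t, a)}\Bigr]
  - \lambda \sum_n \lvert r^{(n)}\rvert, \qquad 0 \le \gamma^{(n)} < 1.$$

The objective is concave in the rewards at fixed discounts, so the fit
nests a convex inner solver inside a grid search over
$\gamma^{(1:N)}$ with step $\epsilon$ (default $0.02$ on
$[0, 0.98]$), which locates the optimum to $\epsilon$ precision per
coordinate.  The inner solver is damped Newton when $\lambda = 0$ and
proximal gradient (FISTA with backtracking and soft-thresholding, so
zeros are exact) when $\lambda > 0$; both stop when the objective
changes by less than a relative $10^{-8}$ (cap 10000 iterations).
Rewards start at zero; within the grid search each node warm-starts at
its predecessor's solution.

```{r}
library(modirl)
subjects <- sample_subjects(1, seed = 1)
cohort <- simulate_dataset(subjects, tasks = 4, trials_per_task = 4,
                           seed = 1)
fit <- mirl(cohort$data)
summary(fit)
plot(fit, "profile")
```

### Grid-search strategy

`search = "exhaustive"` enumerates every $\gamma$ combination
($50^N$ nodes at the defaults).  Because one convex solve per node makes
this expensive for $N = 3$, the default (`"auto"`) switches to a staged
search above 20000 nodes: an exhaustive pass over a uniformly thinned
grid (about 1000 nodes), then hierarchical refinement around the three
best nodes at successively finer strides down to the full $\epsilon$
resolution.  On every dataset where we compared them, the staged search
returned the identical optimum at roughly a fiftieth of the cost (a
regression test asserts the equality on a three-module fit).
`refine = TRUE` adds one local $\epsilon/4$ pass around the optimum.
The likelihood profile in each $\gamma$ is smooth in this model family,
which is what the thinned first pass relies on; `"exhaustive"` remains
available when that assumption is in doubt.

### Identifiability

Two structural degeneracies shape what can be estimated.

* Only the product $\eta\, r^{(n)}$ enters the likelihood, so $\eta$ is
  fixed at 1 during fitting and the reward scale absorbs the decision
  maker's confidence.  Recovery claims are therefore stated on
  *normalized* rewards (absolute values summing to one).
* Within a module, $(r, \gamma)$ forms a ridge: over a narrow band of
  object distances, lowering $\gamma$ and raising $r$ changes action
  preferences very little.  The ridge's curvature — hence the precision
  of $\hat\gamma$ — grows with the spread of distances at which the
  module measurably influences choice.  A module whose true reward is
  near zero has an unidentifiable discount, which is why the cohort
  generator keeps every module's weight above a floor (see below) and
  why recovery reports exclude zero-reward modules from the
  $\gamma$ error.

## The synthetic cohort generator

No human data ships with the package; the generator emulates the
behavioral study so that every stage is testable end to end.  Each trial
gets a fresh seeded environment: a smooth random path (4–6 spline
control points with a gently meandering vertical profile, arc-length
resampled at one cell so consecutive waypoints are one step apart) and
12 targets plus 12 obstacles placed uniformly with at least one cell of
separation, kept one cell clear of the waypoints so the path is
walkable.  Subjects share the per-trial environments, as in the study.

Each synthetic subject owns one base weight vector over
(target, obstacle, path), one discount per module, and one behavioral
$\eta$, shared across the four task conditions; instructions only
rescale task-irrelevant modules (factor 0.2 — mirroring the residual
obstacle avoidance seen under irrelevant instructions — with the
obstacle reward negative).  This shared-parameter structure is the
regime in which cross-task synthesis of the combined condition from the
two two-task conditions is exact.

Defaults, chosen once to realize the study's qualitative conditions and
then left alone:

* base weights: Dirichlet$(2, 2, 3)$ (path weighted highest, as in the
  human estimates), rejected until every weight is at least 0.12 — the
  floor mirrors the human cohort, where every module retains
  appreciable normalized weight, and keeps each $\gamma$ identifiable;
* discounts: path $\sim U(0.88, 0.96)$ (high and stable), target
  $\sim U(0.60, 0.85)$, obstacle $\sim U(0.55, 0.80)$.  Target
  discounts much above 0.85 give distant targets room-wide pull and
  produce stranded, non-terminating agents, which the study's
  goal-terminated trials rule out;
* behavioral $\eta \sim U(3, 8)$ with unit-sum rewards.  Below
  $\eta \approx 2$ the choice field far from attractors is nearly
  uniform and trials become diffusive random walks that rarely reach
  the goal;
* rollout cap 2000 steps, high enough that essentially every trial ends
  at the goal naturally.  Regenerating capped rollouts would condition
  the sample on goal completion and bias estimation, so the cap is a
  guard, not a filter.

Typical trials run tens to a few hundred decision steps, bracketing the
study's ~100 samples per trial.

What the generator does **not** emulate: gaze and body kinematics,
reaction-time structure, order effects across tasks, and any human
deviation from the softmax-of-summed-potentials policy.  Passing
recovery tests therefore demonstrate that the estimator inverts the
model class correctly at realistic sample sizes — not that the model
captures everything humans do.

## Numerical and geometric choices

* The agent's position is continuous; the grid sets step length,
  waypoint spacing, and value-surface resolution.  The $22.5°$ headings
  leave any lattice immediately, so a continuous pose avoids lattice
  artifacts while honoring the discretization.
* Walls clip movement (the component of a step beyond a wall is lost).
* Consumption radii: half a cell for targets and obstacles (collision),
  one full cell for path waypoints (a corridor half-width: a waypoint
  counts as visited when the agent walks along the path, not only when
  it steps exactly onto it).  With the half-cell radius applied to
  waypoints, agents frequently pass one just outside the radius, and
  the stale waypoint later pulls them backward into oscillation.
* $0^0 := 1$, so a myopic module ($\gamma = 0$) still values immediate
  interception.
* Greedy ties break toward the lowest action index, making evaluation
  deterministic; softmax sampling is the stochastic pathway and is
  always seeded.
* All live objects of every module enter the Q sum (the default); a
  per-module `nearest_k` window is available for experimentation.  Note
  that short windows on the path module narrow the distance band that
  identifies $\gamma_{\text{path}}$ and are not recommended for
  estimation.
* Degenerate inputs: empty modules contribute zero; all-zero rewards
  give the uniform policy exactly ($\log$-likelihood $-T \log K$);
  normalizing an all-zero reward vector is an error.

## Baseline agents

The ablations keep the evaluation harness agent-agnostic: every agent
answers "what would you do in this observed state?"

* **Binary reward**: rewards clamped to task-relevance signs
  ($\pm 1$ / 0); only the relevant modules' discounts are estimated, by
  the same grid search.
* **Fixed discount**: all discounts pinned to one value (0.1, 0.5 or
  0.99 in the comparison protocol); rewards estimated by the convex
  solver.
* **Bayesian IRL (non-modular)**: a documented reconstruction of a
  classic Bayesian IRL agent with fixed discount (default 0.99).  The
  joint state is the agent's grid cell; objects are held static; the
  reward of a cell is linear in per-module object-occupancy counts so
  the learned weights transfer to the held-out environment; the
  Boltzmann likelihood uses Q from the joint MDP's fixed point,
  computed by policy iteration with exact evaluation (the reported
  residual is the one-sweep Bellman residual, at machine precision at
  convergence); a Gaussian prior ($\sigma = 5$) regularizes the MAP
  weights.  Ignoring consumption and modular structure is the point of
  the baseline: it pays for the joint state space with a coarser model.

## Evaluation protocol

* **Angular difference**: place the fitted agent in every observed
  state, take its greedy action, and average the absolute circular
  difference to the observed heading (degrees, in $[0, 180]$; a
  uniform-random reference averages exactly $90°$ over 16 bins).  A
  softmax-expected variant exists but greedy is the default.
* **Interception counts** per module at trajectory end.
* **Trajectory clouds**: seeded softmax rollouts from the trial's start
  (default 100), with a per-cell visit-density field for overlays.
* **Leave-one-out**: fit on all-but-one trials of a subject-task group,
  evaluate on the held-out trial's novel environment; groups with one
  trial are skipped with a warning.
* **Cross-task synthesis**: target parameters from the path+target
  condition, obstacle from path+obstacle, path averaged, rewards
  re-normalized; compared against a direct fit of the combined
  condition.

## Validation study sizes

The test suite validates the estimator at sizes chosen for precision:
parameter recovery uses 10 replicate subjects with 80 trajectories per
fit (the information in this task geometry puts the per-module
$\hat\gamma$ standard deviation near $0.02$ only above roughly
$15{,}000$ decision steps; `recovery_report()` exposes the full
error-versus-data curve); cross-task synthesis is compared on cohort
means over 12 subjects with 24 trials per condition, since the
per-subject comparison stacks two independent estimation noises; the
model-comparison benchmark uses 10 replicates of the study's own
4-trials-per-condition design; and the oracle-equivalence checks run on
instances small enough for exhaustive search.
`scripts/acceptance.R` re-runs a compact version of the whole pipeline
from a single seed.

On the model-comparison benchmark, the two large effects are robust in
our replicates — the binary-reward agent beats the fixed-discount
agents, which beat non-modular Bayesian IRL, in nearly every replicate
— while full-model-versus-binary is a statistical near-tie at three
training trajectories: the full model's extra flexibility (estimated
reward magnitudes) buys little once the relevance signs and the
discounts are right, and costs estimation variance at small samples.
The corresponding strict four-way ordering check in the test suite
fails more often than not on the first link and is retained as a known
limitation.  A contributing factor is the generator itself: iid softmax
subjects disagree with any deterministic reference policy by tens of
degrees even at high confidence (adjacent-heading value gaps are tiny
and flat-field steps numerous), compressing the gaps between agents
toward zero; smooth, momentum-carrying walkers separate the models far
more clearly.

## Known limitations

* The discount grid is bounded at 0.98; behavior generated by
  $\gamma > 0.98$ would be attributed to the boundary.
* The $(r, \gamma)$ ridge means small-sample fits can trade reward
  scale against discount within a module; compare fits on normalized
  rewards and prefer pooled data when discounts matter.
* The Bayesian IRL reconstruction is deliberately simple; it anchors
  the qualitative comparison, not a faithful replication of any
  specific prior implementation.
* Module definitions (which objects form a module, and that modules
  combine additively) are fixed by hand, as in the modeling framework
  the package implements.
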