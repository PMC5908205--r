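---
title: "Multi-strategy spatial navigation: model and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-strategy spatial navigation: model and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

watermaze simulates a rodent solving Morris water-maze tasks with a modular
controller: several learning systems each propose a movement orientation at
every timestep, and a learned gating network picks one winner. This vignette
explains the model, the choices made where the design was genuinely open,
the parameters that matter, and what the simulations do and do not show.

## The agent and its world

The arena is a disk (radius 100 cm by default); the agent is a 15 cm
diameter disk whose centre must stay inside the wall, moving 6 cm per
timestep in the direction selected for it. A trial ends when the agent
centre enters the platform disk (radius 5 cm), which delivers reward 1;
after 350 timesteps without success the agent is guided straight to the
platform (flagged, and excluded from selection statistics), so that every
rewarded trial ends with a terminal learning update. Wall contact slides the
agent along the wall rather than stopping it: the displaced angular
coordinate is kept and the radius clamped, which never traps the agent. The
arena and platform sizes are package defaults chosen to match the typical
scale of the modelled tasks (the step length and trial cap fix the time
scale); all are configurable.

## Perception

Two population codes form the input (the "entorhinal" vector):

* **Grid cells** (27 = 3 scales x 9 phases): the standard three-plane-wave
  interference pattern, rectified and scaled to `[0, 1]`, a deterministic
  function of true position. Path integration is assumed perfect. Scales
  default to 40/60/85 cm with distinct orientations.
* **Cue cells** (12 per landmark): a ring of bearing-tuned cells (Gaussian
  tuning, width pi/8) multiplied by an exponential distance decay
  `exp(-d/lambda)`. Proximal cues use `lambda = 50` cm. Distal cues use
  `lambda = 500` cm, so they act almost purely as directional references: a
  heading-vector code. This matters behaviourally — with a short distal
  lambda, cue-guided modules can triangulate position from distal landmarks and
  the cue-only model stops showing blocking when the proximal cue is
  removed, contrary to the lesion phenotype the model is meant to produce.
* A **grid gain** of 0.3 balances the energy of the two segments. The cue
  segment disambiguates the residual lattice aliases of the grid code;
  without it, distant positions occasionally share near-identical input
  patterns and the place code becomes multi-stable.

Invisible cues silence their block. A module whose whole input population is
silent emits an *invalid* proposal: it carries no information, takes no part
in selection and receives no gating update. This is what makes test trials
with a removed proximal cue meaningful for its Direction module.

## The cognitive map

Place cells (1000) are learned by competitive Hebbian learning while the
agent performs a 1000-step random walk before the experiment: at each step
the `k = 10` most active cells move their (unit-norm) weight rows toward the
current input, with a per-cell annealed rate `rate / (1 + wins)` so that
each cell converges to the mean of the patterns it won (online
vector-quantisation) instead of chasing the most recent one. Population
activity is rectified, sparsified by k-winner-take-all (50 of 1000 cells
active) and divisively normalised; the sparseness emulates the dentate code
and is required for the downstream graph competition to separate locations.

Graph cells (a pool of 100) then quantise the place code with
novelty-gated recruitment: whenever no committed cell matches the current
place-cell pattern above a vigilance threshold (cosine 0.8), the next fresh
cell commits to it; otherwise the best-matching cells are refined by the
same annealed Hebbian rule at a low rate. Plain competitive Hebbian learning
without recruitment collapses here: because the code is non-negative, every
update also increases a winner's response everywhere, and a handful of
generalist cells end up winning the whole arena. Recruitment is the
incremental-map construction used by the topological-map models this module
descends from, and it guarantees the graph tiles exactly the regions the
walk visited.

Edges are added between consecutive distinct winners while replaying the
walk — two nodes are linked exactly when the agent moved between the
locations they represent without a third winner in between. Node centroids
are activity-weighted mean positions over the steps a node won. Map
learning never sees reward.

## The strategies

All strategies speak one currency: a proposed allocentric movement
orientation.

* **Direction** (one module per assigned cue): TD Q-learning from the cue's
  12 cue cells to 36 action cells with preferred orientations `2*pi*i/36`.
  The proposal is the greedy argmax; exploration is *not* softmax noise but
  a separate module. Every module is updated as if it had selected the
  executed action: the executed orientation is mapped to the nearest action
  cell and the one-step Q-learning update applied (discount 0.9).
* **Locale**: the same learner with the place-cell population as input — a
  model-free place strategy with no graph and no planning. Its input vector
  is unit-normalised (a divisive gain control) so that the TD step size is
  scale-free; without it, linear Q-learning over the ~50-dimensional active
  place pattern is unstable at useful learning rates.
* **Planning**: model-based. When the platform is found, the goal node and
  exact goal position are memorised and goal values `G = alpha^d` (alpha =
  0.9) are spread over the graph by iterating `G_i <- alpha * max`
  over neighbours to a fixpoint (activation diffusion; equal to devaluing by
  graph distance). The module steers toward the centroid of the current
  node's best-valued neighbour — evaluated from the agent's current position
  toward that waypoint, which avoids the orbiting that a fixed per-node
  direction produces — and, at the goal node, toward the memorised goal
  position. Until the first reward the module has no goal and proposes
  nothing. One rewarded trial suffices to re-point the whole graph.
* **Exploration**: a uniform random orientation, kept for three consecutive
  executed steps once selected (persistence prevents dithering); persistence
  is consumed only when Exploration actually controls the movement.

## The gating network

One value unit per registered module, over the concatenation of all cue-cell
activities and the graph-node activities. Selection is hierarchical
winner-take-all: first among the valid Direction modules, then between that
winner, the place-based module and Exploration (ties: place-based >
Direction > Exploration, then lowest index). Learning is TD Q-learning on
the selected unit's prediction error, with the update generalised across
modules by the cosine of the angle between each module's proposal and the
executed movement: a module that proposed the executed orientation is
reinforced fully, one that proposed the opposite is reinforced with the
opposite sign. The cosine is the minimal kernel with those two endpoints.
The bootstrap uses the maximum over all units at the next state.

The model's two free parameters are the Direction and gating learning
rates, calibrated per task within a small range (all other constants are
shared): defaults are 0.1/0.05, with 0.1/0.1 for the cue-place competition
task and 0.05/0.1 for the generalization-gradient task. These are the
operating points at which the strategy-share statistics the study reports
are approached; `experiment_rates()` documents them and any explicit
override wins.

## Protocols, analyses, numerical choices

The six protocols are generated programmatically (see `build_protocol()`),
with pseudo-randomised start positions from four wall positions and seeded
platform schedules without immediate repeats. Probe trials (competition,
gradient, extinction, blocking test) record full trajectories. Occupancy
statistics use sectors (octant = 45 degrees, quadrant = 90 degrees) centred
on the relevant landmark or platform bearing; chance levels are measured
empirically with a `chance` group consisting of Exploration only, not
assumed. The before/after phase split of a probe trial cuts at the first
entry into the reference region, so the phases partition the trial; a trial
that never enters reports an empty after-phase. Responder classification on
the competition trial uses a disk of twice the platform radius around the
old platform centre: entering it before reaching the new platform makes a
place-responder.

Group comparisons use a Mann-Whitney test and within-group contrasts a
Wilcoxon signed-rank test, both implemented with mid-ranks and exact
enumeration (subset-sum dynamic programming for the rank-sum distribution;
all sign assignments for the signed ranks) up to desk-scale sample sizes
(`n_a * n_b <= 400`, `n <= 12`), then a normal approximation with tie and
continuity corrections. Two-sided p-values are twice the smaller tail,
capped at 1.

Everything is deterministic given a master seed: each repeat derives a
fixed sub-seed, and all randomness (weights, walks, start orders,
exploration draws) flows through R's generator, including inside the
compiled engine.

Simulation sizes follow the study design: 50 repeats per group for the
probe-based experiments, with the learning-curve contrasts also checked at
20 repeats in the test suite; those sizes give standard errors a few
percent wide for occupancy fractions, which is the resolution at which the
qualitative contrasts (above chance / at chance) are read out.

## What the generator emulates — and what it does not

The synthetic agent reproduces the *task structure* of the six paradigms:
geometry, cue schedules, platform schedules, trial counts and probe
timings. It does not emulate swimming dynamics, momentum, visual occlusion,
odometric noise, inter-trial intervals, or motivational state. Passing
simulations therefore speak to the computational claims — which strategy
compositions can and cannot produce reference memory, one-trial
re-planning, cue/place competition, generalization gradients and blocking —
not to quantitative fits of rodent swim paths.

## Known limitations

* The map is built once, before the task; there is no online re-learning,
  replay, or map extension during trials.
* With a 1000-step walk the graph covers the arena coarsely (typically
  30-60 recruited nodes); planning paths are correspondingly coarse, and
  the first-trial planning latency depends on how well the goal region is
  tiled.
* Strategy-share statistics (which module is selected where) have high
  between-agent variance; they are reported as means over 50 repeats and
  should be read with their standard errors.
* The winner-take-all selection is noiseless; all stochasticity in
  behaviour comes from the Exploration module and the random
  initialisations.
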