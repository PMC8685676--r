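---
title: "spinchoice: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinchoice: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the estimators, the defaults, and the places where a design
was genuinely open and a choice had to be made. It states no empirical
number that the test suite or the acceptance script does not itself
compute.

# The embodied spin model

## Assumptions

The decision-maker carries an egocentric vectorial representation of the
`k` spatial options. Directionally similar representations reinforce one
another; dissimilar ones inhibit. We model this with `N` binary spins,
each permanently assigned to one target and carrying a unit goal vector
that always points (noisily) from the agent's *current* position to that
target. Energy and dynamics are

* `H = -(k/N) * sum_{i != j} J_ij * s_i * s_j` over ordered pairs,
* `J(theta) = cos(pi * (theta/pi)^nu)`, `theta` the angle between the two
  preferred directions,
* Metropolis proposals (one uniformly chosen spin per proposal, flip
  accepted with probability `min(1, exp(-dH/T))`),
* consensus velocity `V = (v0/N) * sum_i p_i * s_i`, so speed is bounded
  by `v0`.

The model is deliberately minimal: no spiking units, no continuous
neural field, no learning. Its point is the *recursive interplay* between
the network's collective state and the geometry the agent experiences,
which changes as it moves.

Two structural facts shape everything downstream and are worth stating
explicitly because they drove several preset choices below:

1. `J(theta) > 0` out to a tuning-dependent angle (≈ 67° at `nu = 0.7`,
   ≈ 32° at `nu = 0.4`). Options separated by less than this angle
   support each other: they act as a single perceived option.
2. A coalition of mutually aligned active spins of size `m` can only be
   silenced by opposing spins whose inhibition outweighs `m - 1` units of
   mutual support. Majorities are therefore extremely stable — which is
   the mechanism behind both the decision regime's robustness and the
   cluster-allocation choice for the asymmetric moving scene.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `n_spins` (N) | network size | 60 | small enough for quasi-phase-transition behaviour, divisible by 2 and 3 |
| `nu` | neural tuning exponent | 0.7 | the value used for the moving-target scenes; see presets for the three-choice exception |
| `T` | Metropolis temperature | 0.25 | below the operational critical noise located by the phase module (see below) |
| `sigma_e` | directional-noise circular SD (rad) | 0.3 | the stated noise of the moving-target scenes; adopted package-wide |
| `v0` | speed constant (length/step) | 0.1 static presets, 0.01 moving | dimensionless scene at target distance 10; meter-scale scene |
| `neural_steps_per_move` | proposals per movement step | `10 * N` | enforces the neural ≫ movement timescale separation |
| `burn_in` | proposals before the first move | `neural_steps_per_move` | removes the random-initialization transient |
| `stop_radius` | capture distance | 0.25 (static presets) | ≈ 2.5 movement steps; the global `sim_config` default is 0.01 for meter-scale scenes |
| initial states | i.i.d. Bernoulli(1/2) | — | symmetric, unbiased |

Spins are split equally over targets (`N/k`; an error if indivisible).
Unequal preference is expressed through the explicit `allocation`
argument, which is also how the perceptual-cluster allocation of the
moving presets is implemented.

The directional noise is applied per spin at every goal-vector refresh
(not to the consensus vector), as a wrapped Gaussian rotation of the true
bearing. Goal vectors are refreshed synchronously once per movement step;
whether the original simulations refreshed continuously during neural
updates is unknown, and the synchronous choice is the cheaper and simpler
of the two.

If the agent lands exactly on a target the bearing is undefined; the
simulator resolves this by capture (the capture check runs before the
refresh), and `refresh_goal_vectors()` called directly on a coincident
position throws rather than silently substituting a direction.

# Phase-diagram methodology

The compromise-to-decision transition is characterized on a frozen
geometry: agent pinned at the origin, two spin groups with noiseless
preferred directions separated by the inter-target angle `theta`.

**Order parameter.** `m = (n1 - n2) / (n1 + n2)` over active spins,
0 when nothing is active: 0 = compromise, ±1 = pure decision. The source
analysis's exact choice is not recoverable; this one is declared and used
consistently, and is antisymmetric under group relabelling by
construction.

**Regime labels.** `decision` when the chain's mean |m| ≥ 0.5;
otherwise `compromise` when mean |m| is below 0.75 × the
independent-spin (infinite-temperature) expectation of |m| — in the
compromise phase both groups are coherently active, pinning |m| *below*
even the independent null — and `disordered` otherwise (|m| at the null
level means uncorrelated spins). The null expectation is computed by a
quick binomial Monte Carlo at the same `N`.

**Equilibration.** Chains are thinned every `N` proposals, the first
half is discarded, and a split-half diagnostic (`equil_gap`) flags
insufficient equilibration.

**Bistability.** Two angle sweeps at fixed `T`, carrying the spin state
across grid points: one starting from the all-active compromise state and
sweeping up, one from a one-sided decision state sweeping down. A grid
point is bistable when the up-sweep still reads `compromise` while the
down-sweep still reads `decision` — the directional signature of
coexisting solutions. (Any-label disagreement was tried first and is too
fragile: label noise near boundaries produces spurious one-point
intervals.)

**Operational `T_c`.** The midpoint between the last temperature with a
nonempty bistable interval and the first without one. With the default
protocol (N = 60, nu = 0.7) this lands between 0.3 and 0.4, which is why
the package default is `T = 0.25`: comfortably inside the bistable
(robust-decision) regime while still hot enough for decisions to happen
on the session timescale. Note this operational `T_c` is protocol-
dependent — longer dwells at each grid point let the chain escape
metastable states and shrink the interval — and is smaller than the
temperature at which the decision regime itself disappears in fresh-chain
scans.

**Critical angle.** Located two ways at fixed `T`: the susceptibility
peak (`chi = N * Var(m) / T`, population variance, the
fluctuation-dissipation convention) over the angle grid, with a bootstrap
over independent chains for its uncertainty; and the first angle whose
fresh-chain label is `decision`. The acceptance suite checks the two
agree within grid resolution plus bootstrap spread.

# Scenario presets

**Two-choice** (`two-choice`): targets at distance 10, span 30°,
`nu = 0.7`, `T = 0.25`. The compromise stem runs along the bisector and
branches where the subtended angle reaches the critical angle; for these
numbers elementary geometry puts that near x ≈ 7.5, and the fitted break
point lands there.

**Three-choice** (`three-choice`): span 60° and `nu = 0.4`, deviating
from the module default `nu = 0.7`. This is a considered exception: at
`nu = 0.7` the interaction kernel is positive out to ≈ 67°, so a decided
state only becomes stable against reinvasion very close to the targets;
the first elimination never locks in, the centre target (the "glue"
coupled positively to both sides) is always reached, and the sequential
two-branch structure never appears. Sharper tuning (`nu = 0.4`)
stabilizes decided states at mid-range distances; the first elimination
then removes an outermost target essentially always, outcomes split about
evenly over all three targets, and the two branch points are spatially
separated. The per-figure parameter table of the original simulations is
not available; these preset values are declared, not claimed faithful.

**Moving scenes** (`moving-pair`, `moving-asymmetric`): meter scale.
`k` parallel movers travel back and forth along x between ±0.5 m at
0.003 m/step while the follower (v0 = 0.01 m/step) trails them;
`stop_radius = 0` (following, not capture). Lateral positions are
centred so the outermost movers straddle the travel axis. Two choices
here deserve justification:

* *Target speed ≈ v0/3.* The speeds behind the original moving-target
  scenes are not in the available text. At higher target speeds the
  follower, once attached to a consensus position, can never afford to
  detach and re-decide: a session then samples a single position forever.
  At ≈ v0/3 the follower re-engages after every turn-around and revisits
  both consensus positions within one session, which is the reported
  behaviour of real followers. Chosen once and fixed.
* *Cluster allocation.* In the asymmetric scene (gaps 0.09 m and
  0.03 m) the close pair is separated by a few degrees as seen by the
  follower: structurally one perceived option (fact 1 above). With the
  naive equal split the pair would own 2N/3 spins, and by fact 2 a 2:1
  majority bloc can never be silenced: the isolated mover would never be
  visited and the lateral distribution would be unimodal, contradicting
  the two-position structure this scene is known for. The
  equal-attractiveness assumption is therefore applied at the level of
  perceived options: `cluster_allocation()` merges adjacent movers whose
  gap is at most half the largest gap and splits spins equally across
  clusters (30/15/15 here). Scenes with equal gaps, and all static
  scenes, reduce to the plain `N/k` split.

With these choices the follower dwells at two lateral positions — behind
the pair and behind the isolated mover, with comparable occupancy — and
the mode locations are measured, not set: they emerge from the residual
activity of the momentarily losing cluster pulling the follower inward
from the raw target positions.

**Mode estimator.** `lateral_modes()` reports the two highest raw-count
local maxima of the 0.005 m-binned histogram, at least 6 bins apart (the
guard stops one broad peak from being read twice). No smoothing: the
protocol is the literal histogram.

# Trajectory statistics

**Density maps.** Each trajectory's time is normalized to [0, 1]; a
window (default 5% of normalized time, the track-duration convention)
slides in half-window steps; per window the pooled positions are binned,
optionally folded about y = 0 (weight at (x, −y) added to (x, y) before
any normalization, so folding conserves pre-normalization weight), and
scaled to max 1; windows combine cell-wise by maximum and cells below the
threshold (default 0.1 of the map maximum) are zeroed. The per-window
normalization stops slow trajectory phases from dominating the map. The
window length and threshold used originally are unknown; both defaults
are declared and exposed.

**Piecewise branch fit.** `y = 0` for `x <= x_c`, `A (x - x_c)^alpha`
beyond. The break point is profiled on a 40-point grid and refined by
golden-section search; for each candidate the exponent is optimized
numerically on [0.05, 3] and the amplitude is closed-form weighted least
squares, clamped at 0. Deterministic given data and grid. All-zero data
returns `A = 0` with an explicit `unidentifiable` flag rather than an
arbitrary break point. The default fit input is the thresholded density
map's surviving cell centres weighted by cell value (the alternative —
fitting raw trajectory points — is available by passing them directly).

**Randomization test.** The null keeps every trial's x (and time) series
and replaces y values with y values from other random events; the
statistic is recomputed per permutation and
`p = (1 + #{perm >= obs}) / (1 + n_perm)`. Two schemes:

* `pointwise` (default): one global permutation of the pooled y values
  across all samples of all trials. Preserves the x structure and the
  overall y marginal; destroys the coupling between approach progression
  and lateral branching.
* `trajectory`: whole y-series swapped between trials, matched on
  normalized time. This is the scheme one would write down first, but on
  simulated ensembles whose trials share nearly identical x-progressions
  it approaches the identity map — every permuted trial is still a
  coherent branch in the same place — and has essentially no power. It is
  kept for heterogeneous (e.g. experimental) inputs.

The default statistic is the weighted R² of the branch fit (how much
better the critical-point law explains the folded density than a
constant), not the raw amplitude `A`: on pointwise-permuted data the
best-fitting power law can have a *larger* amplitude than the true
branch, so `A` does not rank observed above null; fit quality does. The
calibration suite checks type-I error on pre-shuffled ensembles, where
exchangeability makes the p-value exactly valid.

**Track classification.** `direct` if travel time ≤ 1.5 × the
straight-line time at `v0`; else `wandering` if ≥ 50% of steps move less
than 0.1·v0·dt; else `nondirect`. The three thresholds are declared
configuration (the original criteria are in unavailable supplementary
material).

**Eliminations.** A target is eliminated at the step after the last time
its smoothed (11-step running mean) active fraction reached 0.2, provided
at least 10 suppressed steps remain and some other target is above 0.6 at
that moment. The "last crossing" convention matters: transient dips
during the coalition-churn phase are not eliminations, and an earlier
first-crossing rule mislabelled about a third of three-choice trials
(they later reached the "eliminated" target). The second decision stage
is re-fit by standardizing all trials to the same first-eliminated side,
truncating at the first elimination, and rotating the frame so the
remaining pair's bisector from the mean branch point is the new x-axis.

# The collective analogue

A two-zone flocking model: repulsion (radius 1) has absolute priority;
otherwise attraction to plus alignment with neighbours within the
interaction radius (8), alignment including the agent's own heading.
Informed agents blend the social unit vector with a unit goal vector
weighted by `omega`; headings get wrapped-Gaussian noise (SD 0.02 rad per
step) and turn at most `theta_max * dt` (= 0.2 rad) per step; speed 1,
`dt` 0.1. The blind-angle refinement of richer zonal models is omitted.

The mismatch feedback `omega' = clip(omega + gain*dt*(cos beta - c0), 0,
omega_max)` with `gain = 1`, `c0 = 0.5`, `omega_max = 0.8` implements
"give up a goal you are not achieving": an agent dragged more than 60°
off its goal loses weight, one moving with its goal gains. The gain sets
the give-up timescale (~a few seconds here) and must be fast relative to
the transit time past the decision point, else the group compromises
straight through the gap between targets; `omega_max` caps the tug-of-war
so the group does not fragment (at `omega_max` ≈ 1.2 and above the
informed subgroups tear the group apart). The exact parameter table of
the original collective simulations is unavailable; all values are
declared defaults.

Groups are released in a disk of radius 3 with headings drawn around the
bearing to the targets' centre of mass (SD 0.5 rad) — as released
animals are oriented toward the scene. With uniformly random initial
headings a group first wanders until noise aligns it with some goal,
which adds a long random prologue in front of every trajectory; set
`start_heading_sd = Inf` to get that behaviour.

Splits are detected by single-linkage clustering at threshold 10 (a pair
exactly at threshold is connected); a split ends the replicate. Outcomes
are `target_<j>` (centroid within `stop_radius` = 3), `split`, or
`timeout`.

Without feedback but with uninformed members, opposite goal vectors
average rather than compete: with three options the group is carried to
the central target almost always — the failure mode the feedback
mechanism exists to fix — and the acceptance suite asserts exactly this
contrast.

# What the synthetic scenarios do and do not establish

The generators emulate the *stated world* of the original experiments:
equally attractive options, symmetric geometries (or the stated
asymmetric spacings), an agent released at a distance, noise entering
only through the declared channels. They do not emulate inter-individual
variability (every replicate shares one parameter set), handedness or
other lateral bias, body dynamics or turning kinematics of real animals,
walls and arena boundary effects (moving-target turn-arounds excepted),
or sensory acquisition (targets are always perfectly visible). A green
test therefore establishes that the implemented mechanism produces the
claimed geometry-driven phenomenology — not that any particular animal
parameter was recovered.

Time-budget note: replicate counts in the test suite follow the stated
protocol sizes (500 two-choice replicates, 100 collective replicates);
the Boltzmann-oracle checks run at N ≤ 8 where exhaustive enumeration is
exact; phase scans use coarse grids sized to finish in seconds. The
acceptance report's follower run uses 8 sessions of 4000 steps (≈ 380
following episodes).

# Known limitations

* The order parameter, regime thresholds and operational `T_c` protocol
  are declared conventions; other reasonable conventions shift `T_c`.
* `nu` is preset-dependent (0.4 for the three-choice scene); there is no
  single parameter set under which every figure-style scenario expresses
  its phenomenology, and the original per-figure table is unavailable.
* The trajectory-level permutation scheme is powerless on homogeneous
  simulated ensembles (see above); use the default pointwise scheme
  there.
* The collective model is 2-D, two-zone, without blind angle or
  body-size heterogeneity.
* Mean-field/analytical treatment of the transition is out of scope; all
  critical quantities are Monte-Carlo estimates.
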