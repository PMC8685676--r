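# spinchoice

Simulation and analysis of **spatial decision-making on the move**: how an
animal (or an animal group) steering toward several spatially discrete
options spontaneously reduces the choice to a cascade of binary decisions,
visible as literal bifurcations of its trajectory.

The package is aimed at computational neuroethologists and collective-
behaviour modellers who want a small, fast, fully scriptable
implementation of the embodied ring-attractor-like decision model, the
statistics used to detect trajectory bifurcations, and the matching
collective-motion analogue.

## The model

The agent's directional preferences are a system of *N* binary spins.
Spin *i* encodes the egocentric direction to one of the *k* targets
through a unit goal vector p̂ᵢ and is active (σᵢ = 1) or silent (σᵢ = 0).
The network energy is

    H = -(k/N) Σ_{i≠j} J_ij σ_i σ_j ,
    J_ij = cos( π (θ_ij / π)^ν ) ,

where θᵢⱼ ∈ [0, π] is the angle between preferred directions and
ν ∈ (0, 1] is the neural tuning: ν = 1 gives plain cosine interactions,
ν < 1 concentrates excitation on similar directions (local excitation,
long-range inhibition). States evolve by Metropolis dynamics at a neural
noise temperature *T*, and the agent moves with the consensus velocity of
the active spins,

    V = (v0/N) Σ_i p̂_i σ_i ,

after which every goal vector is re-pointed from the agent's new position
(with wrapped-Gaussian directional noise of SD σₑ). The recursive loop
between motion and the resulting time-varying geometry produces a sharp
compromise-to-decision transition at a critical inter-target angle θ_c,
provided T stays below a critical noise T_c; with three or more targets
the transition repeats as a sequence of binary eliminations.

Five module families cover the workflow:

* **spin model** — `spin_network()`, `metropolis()`, `simulate_trajectory()`,
  `simulate_replicates()`;
* **phase diagram** — `stationary_scan()`, `detect_bistability()`,
  `estimate_Tc()`, `critical_angle()`, `susceptibility()`;
* **trajectory analysis** — `rotate_to_target_frame()`, `density_map()`,
  `fit_piecewise()` (the branch law y = A|x − x_c|^α beyond the critical
  point), `randomization_test()`, `classify_track()`, `heading_profile()`,
  `lateral_offsets()` / `moving_frame_marginals()` for moving targets;
* **collective analogue** — `simulate_group()` and friends: a two-zone
  flocking model whose informed members weight a goal direction by ω,
  adapted by mismatch feedback `ω' = clip(ω + gain·dt·(cos β − c0))`;
* **scenarios / CLI** — `scenario_preset()`, `run_recipe()`,
  `fixture_generator()`, and the `spinchoice_cli()` umbrella interface.

## Worked example: a two-choice bifurcation

```r
library(spinchoice)
preset <- scenario_preset("two-choice")
preset$targets
#> <target_set> k = 2, static
#>             x        y
#> [1,] 9.659258 -2.58819
#> [2,] 9.659258  2.58819

ens <- simulate_replicates(200, preset$targets, preset$config, base_seed = 1)
ens
#> <trajectory_ensemble> 200 trajectories; outcomes: 1=105 2=95

trs <- lapply(ens, as.data.frame)
amp <- bifurcation_amplitude(trs)
amp$fit
#> <piecewise_fit> x_c = 7.429, alpha = 1.159, A = 1.034 (rss 1.058)

randomization_test(trs, n_perm = 99, seed = 2)$p
#> [1] 0.01
```

Read: 200 agents released at the origin split 105/95 between two equally
attractive targets 10 length units away (a fair coin, as symmetry
demands). The folded trajectory density is flat (y ≈ 0, the compromise
along the bisector) until x_c ≈ 7.4 — the geometric critical angle for
this scene at ν = 0.7 predicts ≈ 7.5 — where it opens as a branch of
amplitude A ≈ 1.0; the permutation test puts the bifurcation's
probability under the y-shuffled null at p = 0.01, the smallest value 99
permutations can resolve.

`plot(amp$map, fit = amp$fit)` draws the density map with the fitted
branch overlaid.

## Command line

```sh
Rscript inst/cli/spinchoice.R simulate --preset two-choice --replicates 50 \
        --seed 1 --out out/
Rscript inst/cli/spinchoice.R phase-scan --nu 0.7 --reps 3 --out phase/
Rscript inst/cli/spinchoice.R collective --targets 3 --feedback off \
        --uninformed 4 --out coll/
```

Every invocation writes its resolved configuration and seed beside its
outputs.

## Further reading

The methods vignette (`vignettes/spinchoice-methods.Rmd`) documents the
model assumptions, every tunable parameter with its default and
rationale, the phase-diagram protocol, the permutation-null design, what
the synthetic scenarios do and do not emulate, and known limitations.
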