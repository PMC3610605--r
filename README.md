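# trailnet

Simulation and analysis of collective path selection by trail-laying,
trail-following agents (ant-like robots) in diamond-loop corridor networks.

Groups of ants connect their nest to food sources through trail networks, and
at an asymmetrical trail bifurcation individual ants preferentially take the
branch that deviates least from their incoming direction. Combined with
pheromone recruitment, this bias helps colonies select short paths. The
question this package's models address is whether that bias requires any
active measurement of the bifurcation's geometry — or whether it emerges
passively when a correlated random walk meets corridor walls. The study
system is a swarm of minimal robots that only (i) move by a correlated random
walk, (ii) avoid obstacles, and (iii) lay and follow light trails that decay
like an evaporating pheromone.

The package provides:

* **Maze geometry** (`build_network()`, `enumerate_paths()`,
  `segment_masks()`): a three-loop corridor network in a symmetrical (S) and
  an asymmetrical (A) configuration, reconstructed from its published
  constraints — 7 start-to-target paths in segment categories {4, 6, 8, 10},
  shortest 86 cm, longest 178 cm, 9 cm corridors, exact 60°/60°
  (S) and 30°/30° + 30°/120° (A) bifurcation angles, identical segment
  lengths across configurations.
* **Continuous-space behavioural simulator** (`simulate_arena()`,
  `bifurcation_choice_assay()`): agents steer every 50 ms by the weighted sum
  of an exploratory vector (uniform ±30° redirections at exponential 3 s
  intervals), a four-sensor avoidance vector and a two-photoreceptor
  trail-following vector, at 40 mm/s, coupled to a pheromone raster
  (800 × 600 cells, 6 cm discs of intensity 7, 255 cap, exponential decay
  with τ = 1800 s every 5 s). Compiled core; bit-for-bit seed-deterministic.
* **Discrete network model** (`simulate_network()`, `run_conditions()`,
  `calibrate_network_model()`): Monte-Carlo agents on the segment graph with
  the nonlinear choice function
  P₁ = (k+C₁)ⁿ / ((k+C₁)ⁿ + (k+C₂)ⁿ)
  and a geometry bias P + 4αP(1−P) toward the direct branch at asymmetric
  bifurcations (2/3 when unmarked, vanishing at saturation), separating the
  roles of pheromone and geometry in foraging efficiency.
* **Analysis pipeline** (`usage_series()`, `classify_path()`,
  `selection_events()`, `stats_suite()`): per-second per-segment intensity
  totals with the 50,000 usage threshold, greedy maximum-intensity path
  classification (categories 4/6/8/10/LOOP/NONE), run-length selection-event
  segmentation, and the χ²/Fisher/Wilcoxon/ANOVA+Tukey statistics.
* **Synthetic data** (`scripted_trajectories()`,
  `random_walk_trajectories()`, `canned_field()`): seed-deterministic
  generators with ground truth, so every pipeline stage is testable without
  hardware.

## Worked example

```r
library(trailnet)

net_A <- build_network("A")
net_A
#> <trail_network> configuration A, 3 loops: 13 nodes, 18 segments, total 332 cm
#>   corridor width 9 cm, areas 22.5 cm hexagons, arena [140 x 105] cm

enumerate_paths(net_A)[, c("n_segments", "length_cm")]
#>   n_segments length_cm
#> 1          4        86
#> 2          4        86
#> 3          4        86
#> 4          6       110
#> 5          8       134
#> 6         10       178
#> 7         10       178
```

Seven possible paths, three of them 86 cm shortest paths, the longest 178 cm.

Individual behaviour — a single agent in an isolated unmarked Y whose
branches deviate 30° and 120°:

```r
bifurcation_choice_assay(c(30, 120), n_trials = 1000, seed = 1)
#> <choice_assay> 30/120 deg Y-corridor: 728/995 = 73.2% first branch
#>   (95% CI 70.3-75.9%), 5 timeouts
```

With no pheromone and no geometry sensing, the correlated random walk alone
takes the direct branch ~73% of the time — statistically compatible with the
robots' observed 107/145 = 74%.

Collective efficiency — the four-condition network-model experiment
(configuration S/A × pheromone off/on, 1000 runs each, successful trips =
returns to the start area after visiting the target):

```r
run_conditions(build_network("S"), net_A, n_runs = 1000, seed = 1)
#> <condition_summary> 1000 runs per condition
#>   medians: S-P=151  A-P=162  S+P=192  A+P=293
#>   ratios : A-P/S-P=1.073  S+P/S-P=1.272  A+P/A-P=1.809  A+P/S+P=1.526
```

Geometry alone helps a little (×1.07), pheromone alone helps moderately
(×1.27), and together they interact super-additively (×1.81 in A): the
forward bias keeps recruitment from locking onto loops.

Full-arena emergence — a one-hour swarm of 10 agents in configuration A,
classified second by second:

```r
sim <- simulate_arena(net_A, n_agents = 10, duration = 3600, seed = 1)
cats <- classify_series(sim$usage, net_A)
selection_events(cats)
#>   category start duration
#> 1     NONE     0      342
#> 2        4   342     3259
segments_used_plateau(sim$usage)
#> [1] 14.02419
```

After ~6 minutes of dispersion the swarm locks onto a 4-segment shortest
path and keeps it for the rest of the hour; about 14 of the 18 segments stay
above the usage threshold (fewer than in configuration S — the ordering, not
the absolute level, is the comparable quantity on this reconstructed maze).

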