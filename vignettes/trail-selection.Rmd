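---
title: "Collective path selection by trail-laying agents in corridor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective path selection by trail-laying agents in corridor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system

`trailnet` models a group of small trail-laying, trail-following robots
foraging between a start area ("nest") and a target area ("food source")
through a maze of 9 cm corridors arranged as interconnected diamond-shaped
loops. Trails are virtual: a projector paints light discs along each robot's
track, the painted image accumulates (capped at 255 per pixel), and the whole
raster decays exponentially with characteristic time $\tau = 1800$ s,
re-evaluated every 5 s. Robots sense the local light gradient with two lateral
photoreceptors and steer toward brighter ground, so the light field plays the
role of a recruitment pheromone.

The scientific question the system probes is whether an individual bias
toward the *least deviating* branch at an asymmetrical bifurcation — observed
in trail-following ants — requires any measurement of the bifurcation's
geometry, or whether it emerges passively from the interaction of a
correlated random walk with corridor walls. The package therefore contains
two models and an analysis pipeline:

* a **continuous-space behavioural simulator** (`simulate_arena()`,
  `bifurcation_choice_assay()`): agents integrate three weighted vectors
  every 50 ms — exploration, obstacle avoidance, trail following — inside the
  corridor polygons, coupled to the pheromone raster;
* a **discrete stochastic network model** (`simulate_network()`,
  `run_conditions()`): agents hop between graph segments, choosing branches
  by the classical nonlinear pheromone response with an explicit geometry
  bias at asymmetric bifurcations, which separates the contributions of
  pheromone and geometry to foraging efficiency;
* the **analysis pipeline** (`usage_series()`, `classify_path()`,
  `selection_events()`, `stats_suite()`): per-second per-segment intensity
  totals, a greedy maximum-intensity trace that classifies which path the
  swarm is collectively using, run-length event segmentation, and the
  associated statistics.

## Reconstructing the maze

The corridor network is specified in the literature only through its
constraints: seven start-to-target paths that never reuse a segment, path
categories of exactly {4, 6, 8, 10} segments, shortest path 86 cm, longest
178 cm, every bifurcation binary (both branches deviating 60° from the
incoming direction in the symmetrical configuration S), identical per-segment
lengths in the flattened asymmetrical configuration A, 22.5 cm hexagonal
start/target areas, and a 140 × 105 cm arena. No coordinates or segment
tables are printed.

We therefore searched the space of planar corridor graphs (junction degrees
≤ 3 away from the areas, parallel corridors allowed) for topologies meeting
*all* of those constraints simultaneously. Exactly one topology class
emerged: the start hexagon has two exit corridors, the target one; eleven
binary bifurcations connect 18 segments, two pairs of which are the parallel
arms of diamond loops. The seven paths comprise **three** 4-segment shortest
paths (86 cm each), one 6-segment (110 cm), one 8-segment (134 cm) and two
10-segment paths (178 cm). Several shortest paths are consistent with the
source system, which is described as selecting "one of the possible shorter
paths".

Coordinates are then built deterministically: junction positions were placed
by hand subject to automated checks (≥ 9.5 cm clearance between non-adjacent
corridor centerlines, arena bounds, hexagon separation), and each segment is
routed as a cubic Bézier that leaves its bifurcations along *exact* template
stub directions — 0°/±120° in S; 180°/+30°/−120° (up to rotation and
mirror) in A, which yields the 30°/30° symmetric side and 30°/120°
asymmetric side — with the control-point distance solved by bisection so the
arc length equals the stored segment length to machine precision. The A
configuration re-angles the branches around each bifurcation while keeping
every length identical to S, which is how the physical flattening of each
loop preserves segment lengths. All of this is checked by the test suite
(path census, 86/178 cm extremes, exact deviation tables, arc-length
agreement, clearances).

One consequence of reconstruction from constraints: quantities that depend on
the *number and arrangement* of segments — most visibly the plateau number of
segments in use (below) — are comparable to the source system only up to its
unprinted segment count.

## The behavioural model and its parameters

Each agent updates at `tick` = 50 ms and moves at most
`speed` × `tick` = 2 mm per tick. Heading is set to the direction of

$$\mathbf{D} = w_e \mathbf{E} + w_a \mathbf{A} + w_f \mathbf{T}$$

with the convention that a vanishing resultant keeps the previous heading.

* **Exploration** $\mathbf{E}$: a unit vector re-aimed at exponentially
  distributed intervals (mean 3 s) by a uniform turn in ±30°. Inverse
  transform sampling on the seeded generator replaces the original
  integer-only hardware algorithm; the distribution is the same.
* **Avoidance** $\mathbf{A}$: four proximity sensors at +45°, −45°, 0°, 180°
  with 3 cm range; each contributes a vector opposite its heading with
  magnitude $1/(1+\exp((d-1.5)/0.3))$ of the obstacle distance $d$ in cm
  (midpoint and slope are free constants; only "approximately sigmoid" is
  specified). Other agents are obstacles too (robot radius 1.1 cm).
* **Trail following** $\mathbf{T}$: two photoreceptors at ±1.1 cm lateral
  offset sample the raster (1 cm radius, scaled by the 255 cap) and pull
  laterally toward the brighter side.

Weights default to $w_a = 2$, $w_f = 1$, $w_e = 0.5$ (avoidance must
dominate so walls are never penetrated; following must dominate exploration
for trails to recruit). Wall contact is additionally resolved by a hard
no-penetration projection onto the corridor domain (a signed-distance grid at
raster resolution), because pure force schemes can tunnel at 50 ms steps.
Containment, the 2 mm speed bound and bit-for-bit seed determinism are
asserted by the tests at every recorded tick.

Deposition follows the tracking loop: every 0.2 s a marker-on agent may lay a
6 cm disc of intensity 7, skipped unless its center is at least one disc
diameter from the same agent's previous disc. Markers are off inside the
start/target hexagons (detected geometrically). Evaporation multiplies the
raster by $e^{-5/1800}$ every 5 s. The float-mode raster used for analysis
is exactly multiplicative; the 8-bit dialect truncates to integers, flushing
sub-unit residues.

### The individual-choice assay

`bifurcation_choice_assay()` releases one agent per trial into an isolated
Y-corridor whose branches deviate 30° and 120° (or 60°/60° as a control),
with no pheromone, and records the branch whose corridor the agent occupies
12 cm past the junction. Release conditions are the assay's calibrated free
parameters: the agent starts 25 cm before the bifurcation with a uniform
heading perturbation of ±65° around the corridor axis, standing in for
arrivals from the maze's curved corridors, which are far from axis-aligned.
With these settings the direct-branch proportion is 72–74%, statistically
compatible with the observed robot counts (107 of 145), and the symmetric
control stays at 50%. A perfectly aligned release would give ≈88% — the bias
is strongly controlled by arrival alignment, which is worth remembering when
comparing corridor systems.

### What the simulator does not capture

Agent motion in corridors is strongly wall-bound: the exploratory direction
pins an agent against a wall for seconds at a time, so residence time
concentrates near walls and especially inside strongly curved corridor
sections. Per-segment occupancy under the pheromone-free null model therefore
correlates with corridor area only loosely (r ≈ 0.4, with densities spread
over a few fold) rather than being strictly uniform per unit area as an
idealized diffusion argument would predict. We deliberately kept this gait:
an experiment that re-aims pinned agents away from walls equalizes occupancy
almost perfectly but destroys collective path selection, because the slow
wall-bound motion is precisely what limits diffusive penetration of the
detour web and lets evaporation prune it. Video-tracking artifacts, motor
dynamics, battery effects and IR communication are out of scope.

## The discrete network model

Time advances in 1 s steps. Agents in an area leave with probability
`p_leave` per second through a uniformly chosen exit corridor (inside the
areas they random-walk with no pheromone). Traversing segment $i$ takes
$\mathrm{round}(l_i/v)$ seconds at $v$ = 4 cm/s. At a bifurcation the agent
chooses between the two other corridors with

$$P_1 = \frac{(k + C_1)^n}{(k + C_1)^n + (k + C_2)^n},$$

and at an asymmetric side the direct branch (30° deviation) receives the
geometry bias $P_\mathrm{direct} = P + 4\alpha P(1-P)$, which equals $2/3$
at $\alpha = 1/6$ when marking is equal and vanishes as the pheromone choice
saturates — the two limits that define it.

Three design choices depart from the most literal reading of the source
description; each was forced by the reconstructed maze and is part of this
package's model:

1. **Marking is per distance.** Entering segment $i$ adds $Q \, l_i/v$
   pheromone (rate `Q` per second of traversal), mirroring the physical
   disc-per-6-cm trail laying. A length-independent per-visit quantity
   over-rewards regions with short segments — on this maze, the detour web —
   and no parameter setting then lets pheromone increase trip counts.
2. **Per-segment saturation `C_cap`.** The projected image caps at 255 per
   pixel, so physical trail strength is bounded. Without the discrete
   counterpart, marked loops become absorbing (the escape probability decays
   to zero as marking grows) and deposition *reduces* successful trips in
   configuration S, to zero in strong-feedback regimes.
3. **Uniform area exits**, per the pheromone-free random walk inside areas.

The through-branch assignment at each bifurcation of configuration A (which
corridor is the 30° continuation as seen from the other two) is part of the
unprinted maze geometry. It is stored with the geometry (`roles` tables) and
was selected so that the *pheromone-free* efficiency ratio between A and S
matches the reported 1.05; everything downstream (branch-angle tables, the
model's decision tables, the flattened stub templates) derives from the same
assignment.

### Calibration

`calibrate_network_model()` minimizes the squared log-ratio error against the
four median-trip ratios (A−P/S−P, S+P/S−P, A+P/A−P, A+P/S+P) by random local
search. The fitted values are persisted as package defaults: $k = 9$,
$n = 2.5$, $Q = 0.12$ s⁻¹, `p_leave` = 0.15 s⁻¹, `C_cap` = 80 (with
$\alpha = 1/6$ fixed by the unmarked 2/3 choice and $\tau = 1800$ s fixed by
the evaporation device). At 1000 runs per condition these defaults give
ratios near (1.07, 1.25, 1.79, 1.53) against targets (1.05, 1.30, 1.80,
1.46); orderings and the super-additivity of geometry × pheromone are
reproduced with rank-sum p-values far below 10⁻⁴. The S+P condition is
bimodal — runs either lock a trail onto a shortest route or lose it to the
web — which makes its median the noisiest of the four quantities.

## Synthetic data

`scripted_trajectories()` shuttles agents along designated paths at 40 mm/s
with AR(1) lateral jitter (default sd 0.5 cm, well inside the 9 cm corridor)
and area dwells, with ground truth attached; `random_walk_trajectories()` is
the pheromone-free null model; `canned_field()` paints exact per-segment
totals for hand-traceable classifier fixtures. All generators are
seed-deterministic and write/read the same CSV/JSON/PGM dialects the rest of
the package uses. Packaged fixtures live in `inst/extdata/`: both network
descriptions, one scripted shortest-path trajectory log, and a battery of
canned-field scenarios covering all seven paths plus loop and no-path cases.
What passing these tests shows is that the *pipeline* is correct; scripted
fixtures do not emulate tracking artifacts (blob merging, dropped frames) or
any robot dynamics beyond the kinematics stated above.

## Numerical choices and degenerate inputs

* Classification ties (two candidate segments with exactly equal maximal
  intensity) break toward the lower segment id, with a warning; ties are
  measure-zero on simulated fields but common on canned ones.
* The greedy trace requires its first segment to *exceed* the 50,000
  threshold (an unmarked network must classify as no-path); "previously
  visited bifurcation" includes the trace's own start; the segment just
  traversed is excluded from candidates.
* The 50,000 usage threshold is in pixel-sum units of the 800 × 600 raster;
  analyses on other raster shapes must rescale, and the float-mode field is
  compared on the same scale.
* A zero steering resultant keeps the previous heading; a zero-agent or
  zero-duration simulation returns empty, well-typed objects.
* Evaporation applies before deposition within each 1 s step of the network
  model, so total pheromone follows
  $\Sigma C(t{+}1) = e^{-1/\tau}\,\Sigma C(t) + \sum_\mathrm{entries} Q\,l/v$
  exactly (before saturation).

## Problem sizes

The shipped tests and the acceptance script use the study's own scales where
they are fast — 1000 single-agent trials for the choice assay, 1000 runs per
condition for the four-condition experiment, 15 replicates × 60 min × 10
agents for the full-arena analysis — and smaller rasters (400 × 300) where
only partition properties matter. A full 15-replicate arena batch runs in
about a minute on one core thanks to the compiled stepper.

## Known limitations

* The maze is a reconstruction: all printed constraints hold, but
  segment-count-dependent quantities (e.g., the plateau of segments in use:
  here ≈15 of 18 in S and ≈14 in A, versus ≈7 and ≈5 on the original,
  smaller network) are comparable only as orderings, which the tests gate.
* Occupancy uniformity under the null model holds only loosely (above).
* The 4-loop variant is an untested courtesy: it satisfies the structural
  invariants (12 paths, consistent categories) but carries no claims.
* The discrete model's trail formation in configuration S is bistable;
  median-based ratios inherit that variability (~±0.05).
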