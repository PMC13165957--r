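---
title: "Adaptive picking-path planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive picking-path planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rosepath)
```

rosepath plans picking tours for selective rose harvesting. A detector has
already found the blooms and buds in an image; what remains is a routing
problem: in what order should a robot arm visit the detected targets so that
the total travel is short, and how much computation is that ordering worth?
This vignette explains the models the package implements, the parameters
that matter, what the synthetic scenes do and do not emulate, and the design
choices made where the problem statement was genuinely open.

## The objective

A scene is a set of waypoints — bounding-box centers in pixel coordinates
(origin top-left, x right, y down, continuous values; no rounding). Blooms
and buds are planned as separate tours by default because they are
harvested for different uses; a combined mode merges them. The objective is
the closed Euclidean tour length

$$ F(p) = \sum_{i=1}^{n-1} d(p_i, p_{i+1}) + d(p_n, p_1), $$

the sum of leg lengths plus the return edge that closes the harvesting
loop. Closed lengths are what all planners report for comparison (the open
path length is recorded alongside); the closed objective is invariant under
rotation and reversal of the visiting order, which the tests exploit.
Coincident duplicate detections are retained — planners must tolerate
zero-length edges, and do.

## Scene complexity and the planner gate

Running a metaheuristic on every scene wastes time on trivial ones. The
gate computes a complexity score from two saturating terms,

$$ c = w_{time}\,\frac{\rho}{1+\rho} + w_{dist}\,\frac{\bar d}{1+\bar d},
   \qquad w_{time} = 0.6,\; w_{dist} = 0.4, $$

with $\rho$ the target density and $\bar d$ the mean pairwise distance.
Each term lies in $[0, 1)$ and is strictly increasing, so $c \in [0, 1)$
and grows with both crowding and spread. The decision tree is:

* $n < 3$: reciprocating traversal (nothing to optimize);
* $n > 20$: genetic planner (sorting is no longer competitive);
* otherwise reciprocating iff $c \le 0.4$, except that bud scenes with
  $\rho > 0.5$ always go genetic (buds grow in tight clusters where a
  serpentine sweep re-crosses the same region repeatedly).

Boundary semantics are literal: `<`, `>`, `<=`, `>` exactly as written.

**Units for $\rho$ and $\bar d$.** Raw pixel units would break the score:
with $\rho = n/\text{Area}$ in px$^{-2}$, $\rho \approx 10^{-5}$ and the
density term vanishes, while a raw-pixel $\bar d$ (hundreds of px)
saturates its term at $\approx 1$. The package therefore measures density
per *reference tile* — by default one percent of the image area, so $\rho$
counts targets per 1%-tile ($\rho = n/100$ for any image size) — and
divides $\bar d$ by the image diagonal before it enters the score. Both
normalizations are configurable (`gate_config(density_ref_frac,
density_ref_area, distance_norm)`) and every report records the reference
area actually used. "Average Euclidean distance" is read as the mean over
all unordered pairs; a nearest-neighbour variant is selectable
(`pair_method`), and the gate's monotonicity properties hold either way.

A consequence worth stating plainly: with the default 1%-tile, $\rho = n /
100 \le 0.2$ throughout the mid range $3 \le n \le 20$, so the score
cannot reach $0.4$ there ($c \lesssim 0.25$) and the bud override
($\rho > 0.5$, i.e. $n > 50$) is subsumed by the $n > 20$ rule. At these
defaults the gate in practice reduces to the two count rules. The full
decision tree is nevertheless implemented and tested as a total function of
$(n, c, \rho, \text{category})$, and both dormant branches become active
under a finer reference tile — e.g. `density_ref_frac = 1/25` makes a
15-bud cluster trip the override. We keep the 1%-tile default because it is
scale-free and puts $\rho$ on an interpretable O(0.1–1) range; users whose
fields are denser than these defaults assume should shrink the tile.

## The planners

**Reciprocating (boustrophedon) traversal.** Points are bucketed into
horizontal bands, bands visited top to bottom, each band sorted by x with
alternating sweep direction. This is a sorting operation, O(n log n), and
runs in well under a millisecond at the scene sizes considered. The band
height defaults to one tenth of the image height (a field-row traversal);
it is a parameter of every call. The serpentine is the fast fallback and
the baseline every other planner must beat.

**Nearest-neighbour construction** seeds the genetic planner: hop to the
closest unvisited point, ties to the lowest index (deterministic).

**2-opt local search** reverses a tour segment whenever doing so shortens
the closed tour, first-improvement, until no move helps. Local optima of
2-opt contain no properly crossing edge pair in the Euclidean plane — the
tests verify this geometrically with an orientation-based segment
intersection check. First-improvement (rather than best-improvement) sweeps
converge faster and the endpoint is equally a local optimum.

**Hybrid genetic planner** (`ga_tour`). Order-based GA on closed tours:

* *Initialization*: a `greedy_seed_fraction` (default 0.2) of the
  population comes from nearest-neighbour constructions at distinct random
  starts; the pipeline additionally injects the reciprocating and
  nearest-neighbour tours; the rest are uniform random permutations.
* *Selection*: elitism (`elite_count = 2` copied unchanged — making the
  best length monotonically non-increasing, an invariant the tests assert)
  plus tournaments of size 3.
* *Variation*: order crossover (OX) at rate 0.9 — the standard
  permutation-safe crossover — and segment-inversion mutation, which
  shares its neighbourhood structure with 2-opt (swap mutation is
  selectable). The mutation probability decays linearly from 0.20 to 0.02
  across the generation budget, shifting from exploration to refinement.
* *Local search*: 2-opt applied to the generation best every 5
  generations and to the final answer.
* *Termination*: at the generation cap, or early after 10 consecutive
  generations without improvement of the best closed length (compared with
  absolute tolerance $10^{-9}$ so floating-point churn cannot reset the
  counter).
* *Budgets*: `dynamic_ga_params(n)` sets $N = \mathrm{clamp}(4n, 20, 120)$
  and $G = \mathrm{clamp}(10n, 50, 400)$. The clamps keep per-scene work
  $O(GNn)$ bounded by a constant times $n^2$, which is what makes the
  planner viable in a real-time loop. The schedule is a package choice
  (only its existence, the patience of ten and the linear decay shape are
  fixed by the method's description); explicit `ga_config()` values
  override it.

All randomness flows from one seed per call; a fixed seed reproduces the
tour bit for bit. Every stochastic entry point takes `seed` and records it.

**Ant system** (`aco_tour`) is a textbook baseline for the benchmark:
construction probabilities $\tau^\alpha (1/d)^\beta$, global evaporation
0.5, deposit $1/L$; ants start on a rotating schedule of cities so the
$\alpha = 0$, large-$\beta$ limit reproduces the greedy construction — a
property used as a test. Defaults ($\alpha = 1$, $\beta = 3$, 100
iterations, one ant per city) are conventional, not tuned.

**Brute force** (`brute_force_optimal`) enumerates the $(n-1)!/2$ distinct
closed tours for $n \le 9$ and is the exact oracle in the tests: the GA is
required never to beat it (impossible) and to match it in at least 95% of
200 seeded runs at $n \in \{5,\dots,8\}$ — the measured rate is 99%.

## The pipeline and its guarantee

`rose_plan()` computes the report, selects the planner, and runs it. When
the genetic planner runs, its initial population always contains the
reciprocating and nearest-neighbour tours; elitism then guarantees
**dominance**: the adaptive result is never longer than the reciprocating
traversal of the same points, on every scene and seed, by construction
rather than by luck. The benchmark harness confirms zero violations over
the full synthetic suite.

`run_benchmark()` mirrors a planner-comparison design: each strategy plans
the same scenes (identical bud/bloom point totals), blooms and buds as
separate tours whose closed lengths are summed per scene. The `ga_plain`
baseline is a deliberate ablation representing a *standard* GA: no greedy
seeding, no 2-opt, constant mutation rate, and conventional fixed budgets
(N = 50, G = 200, no early stop). The hybrid planner's adaptive budgets and
early stopping are part of the method under evaluation, so the baseline
does not inherit them. OX, tournament selection and elitism remain — they
are generic GA machinery, not contributions of the adaptive method.

At the default study size (288 scenes, matching the validation-set size of
the comparison this harness mirrors) the qualitative ordering is stable
across seeds: the adaptive planner's mean closed length is shortest, the
plain GA's is intermediate, and the reciprocating traversal's is longest,
with mean runtimes ordered the other way (milliseconds for the traversal,
tens of milliseconds for the adaptive planner, ~1 s for the fixed-budget
GA). Absolute pixel lengths depend entirely on the synthetic scene
geometry and are not comparable to any particular field dataset.

## Synthetic scenes

No deposited detection dataset exists, so the package generates scenes
(`generate_scene`, `scene_suite`, `benchmark_suite`). Blooms follow a
uniform Poisson process; buds follow a Thomas cluster process — Poisson
parents placed uniformly, Gaussian offspring around them — because buds
grow small, numerous and tightly clustered while open blooms are sparser.
Expected counts default to 21 buds and 6 blooms per scene, the per-image
averages implied by a 6114-bud / 1816-bloom survey over 288 images; the
cluster geometry (4 parents, 25 px spread) and the 4 px minimum separation
are package choices, documented as synthetic rather than calibrated.
Points are rejection-resampled to stay in bounds and honour the
separation; impossible packings raise an error rather than silently
relaxing the constraint. A Clark–Evans index below 1 for generated bud
patterns (and near 1 for blooms) is asserted in the tests as a
distributional sanity check.

The suite profiles — sparse ($2 \le n < 10$, truncated resampling), dense,
clustered buds, large scenes (1280×960, n up to ~150), and gate-boundary
scenes with exact counts 2, 3, 20, 21 — are chosen to exercise every
reachable decision branch and to span $n$ from 2 to about 200 across the
default 288-scene mixture (72/72/96/36/12). What the synthetic scenes do
*not* emulate: detector noise (false or missed detections), illumination
and occlusion effects on detection quality, perspective distortion, or any
3-D structure. Passing benchmarks therefore demonstrate the planners'
behaviour on plausible spatial point patterns, not end-to-end field
performance.

Synthetic boxes get fixed extents (30×30 px blooms, 14×14 px buds), shrunk
near borders only so that YOLO label files renormalize into $[0,1]$;
planning uses centers exclusively.

## Input handling and rescaling

YOLO label files (`class cx cy w h`, normalized) and a JSON detection
schema (pixel bboxes) are both supported; parsing preserves input order,
keeps duplicates, reports the offending line on malformed input, and
carries confidence scores through without using them — tours are planned
on every detected center. High-resolution captures (e.g. 4160×3120) can be
shrunk for processing under a pixel budget (default one megapixel): the
factor is $\sqrt{\text{budget}/\text{pixels}}$, the rule is idempotent,
and the record keeps the original dimensions so planned paths map back to
original coordinates exactly (the coordinate mapping is closed-form; its
round trip is lossless to well under half a pixel). When raw rasters are
processed, a separable Lanczos-3 resampler is provided; no installed
imaging package offers Lanczos resampling, so it is implemented here and
tested on constant and gradient images.

## Numerical choices and degenerate inputs

* Stagnation and dominance comparisons use absolute tolerance $10^{-9}$ on
  lengths in pixels (scenes are $O(10^3)$ px across, so this is ~12
  significant digits below scale).
* Ties: nearest-neighbour and tournament ties resolve to the lowest index /
  first candidate; band sorting is stable on input order.
* $n = 1$ returns the trivial zero-length tour everywhere; $n = 0$ is an
  error (planning undefined); GA and ACO require $n \ge 2$.
* Coincident points give zero-length edges and are handled by all
  planners; the crossing diagnostic skips edge pairs sharing an endpoint.
* The ant system floors distances at $10^{-12}$ when inverting them and
  falls back to uniform choice if all weights underflow.

## Problem sizes in the shipped checks

The test-suite and acceptance-script sizes are the package's own study
conditions: 200 GA-vs-oracle runs at $n \in \{5..8\}$; 100 2-opt geometry
scenes at $n = 12$; the full 288-scene benchmark with strategies
reciprocating / plain GA / adaptive; 1000-draw generator calibration. The
ant system is validated on small instances (it is the slowest baseline by
far, consistent with its known cost) and excluded from the default
288-scene benchmark run.

## Known limitations

* Planning is 2-D in the image plane: no depth, no arm kinematics, no
  obstacle avoidance.
* The gate's score normalizations are declared package defaults, not
  recovered constants; at the 1%-tile default the score threshold and bud
  override are effectively dormant (see above).
* The plain-GA and ant-system baselines are reference implementations with
  conventional settings; comparisons against them characterize this
  package's planners, not any published implementation.
* Benchmark lengths are means over synthetic scenes; only orderings and
  invariants, not absolute pixel values, are meaningful claims.
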