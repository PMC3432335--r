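---
title: "Hybrid swarm optimization and MI-driven rigid registration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid swarm optimization and MI-driven rigid registration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

swarmreg estimates the six parameters of a rigid 3D transform — three
translations and three Euler angles — that align a *moving* medical volume
to a *fixed* one by maximizing the mutual information (MI) of their joint
intensity distribution, using a hybrid particle swarm optimizer (HPSO).
This vignette is the package's methods reference: the model and its
assumptions, every tunable that matters, the design choices made where the
method leaves room, and what the bundled synthetic experiments do and do
not demonstrate.

## The registration model

Registration is posed as metric maximization: with fixed image
$f_1(\mathbf{x})$ and moving image $f_2(\mathbf{x})$ on world coordinates
(mm), we seek

$$\hat{T} = \arg\max_T \; \mathrm{MI}\left[f_1(\mathbf{x}),\, f_2(T(\mathbf{x}))\right],$$

where $T(\mathbf{p}) = R(\alpha, \beta, \gamma)\,(\mathbf{p} - \mathbf{c}) +
\mathbf{c} + \mathbf{t}$ is rigid: a rotation about a fixed center
$\mathbf{c}$ followed by a translation. Six degrees of freedom; no
deformation. The assumptions are those of any rigid MI pipeline: the
underlying anatomy is the same in both volumes up to pose, and intensity
classes correspond (possibly non-monotonically) between modalities.

Conventions, chosen where the formulation leaves latitude and fixed
throughout:

* **Angles in degrees at every interface** (recovered parameters are
  reported the way clinical tables print them); radians only inside the
  rotation-matrix builder.
* **Rotation composition**: `rotation_matrix(a, b, g)` is the transpose of
  $R_x(\alpha) R_y(\beta) R_z(\gamma)$, written out in
  `?rotation_matrix`. A property test asserts $R^\top R = I$ and
  $\det R = 1$ to $10^{-9}$ for arbitrary angle triples.
* **Rotation center**: the fixed volume's world-space center
  (`volume_center()`). Translations are world-space millimetres. Recovered
  translations are only comparable across conventions when the pivot
  matches, so the phantom generator uses the same convention.
* **Resampling**: backward (pull) warping. Every fixed-grid voxel center is
  mapped through $T$ into moving-space and interpolated trilinearly.
  Out-of-field samples take a fill value *and are excluded from the metric
  by a validity mask* — counting them would let the fill bin manufacture
  spurious mutual information.
* **Angular errors are compared without modular wrapping**: a recovered
  149.5° against a 120° truth counts as 29.5°, matching how recovery
  tables are conventionally read.

## The mutual-information metric

MI is estimated from a discrete joint histogram: $B \times B$ uniform bins
(default $B = 64$) spanning each image's intensity range,

$$\mathrm{MI}(A, B) = H(A) + H(B) - H(A, B), \qquad
H = -\sum p \log_2 p .$$

Choices that matter:

* **Bin count** (`bins`, default 64). Fewer bins smooth the metric surface
  but blur distinct tissue classes together; more bins sharpen class
  separation but make the estimate noisier and the surface rougher. 64 is
  a conventional middle ground for volumes of $10^4$–$10^6$ voxels; for
  very small grids (tests use down to $24^2 \times 8$) 32 bins behave
  better and the tests pass `bins` explicitly.
* **Edges fixed per run.** During one registration the bin edges are
  computed once from the two untransformed volumes' global ranges. If the
  edges tracked each candidate's observed range, MI values would not be
  comparable across candidates and the optimizer's best-so-far bookkeeping
  would be meaningless.
* **Log base 2** (bits). Maximization is base-invariant; bits make the
  identities in the test suite (`MI(A, A) = H(A)`, independence gives 0)
  read naturally.
* **The plug-in estimate is a KL divergence, hence non-negative**; the
  implementation floors tiny negative floating-point residue at zero.

The registration objective (`registration_mi()`, and a fused compiled
kernel inside `register_volumes()` that produces identical values) returns
0 when no voxel overlaps; `register_volumes()` raises an error only when
*no* sampled transform ever achieved overlap, advising wider bounds.

## The optimizers

### Particle swarm

Each particle carries a position $x$ (a candidate parameter vector), a
velocity $v$, and its personal best $p$. With group attractor $g$:

$$v \leftarrow w\,v + c_1 r_1 (p - x) + c_2 r_2 (g - x), \qquad
x \leftarrow x + v,$$

with $c_1 = c_2 = 2$ and inertia $w$ decreasing linearly from
$w_{\max} = 0.98$ to $w_{\min} = 0.4$ over the run
($\Delta w = (w_{\min} - w_{\max})/T$ per generation, clamped). The
schedule starts at the *maximum*: a decreasing-inertia swarm explores
first and exploits later; both endpoints are configurable.

### The hybrid: subpopulations and crossover

HPSO adds two genetic-algorithm ingredients:

1. **Subpopulations (islands).** The swarm is partitioned as evenly as
   possible into $N$ groups (default 4 of 56 particles; every group must
   keep at least 2 members). *Within a group the attractor $g$ is the
   group's own best, not the global best* — if all groups chased one
   global attractor they would collapse into a single swarm and the
   partition would confer nothing. The global best is a promotion target
   only: any group best that beats it replaces it, and it is what the
   optimizer finally reports.
2. **Crossover.** Once per generation the two best group leaders become
   parents. Positions mix by arithmetic crossover with one shared uniform
   draw $r$ — $x_i' = r x_i + (1-r) x_j$, $x_j' = r x_j + (1-r) x_i$ — so
   the offspring form a complementary convex pair inside the interval
   spanned by the parents. Velocities recombine speed-preservingly: both
   offspring point along the parents' summed direction
   $V = (v_i + v_j)/\lVert v_i + v_j \rVert$, each keeping its own
   parent's speed ($v_i' = \lVert v_i \rVert V$). When the parent
   velocities cancel exactly there is no common direction and they are
   kept unchanged — a documented degenerate rule. Each offspring replaces
   the *worst* member (lowest personal best; ties broken by lowest index)
   of its parent's group, and that slot's personal best restarts from the
   offspring's own evaluation.

With $N = 1$ the crossover step is skipped and HPSO reduces to plain PSO
step-for-step under the same seed — a property the test suite asserts
exactly.

### Randomness, bounds, and the choices behind them

* **Scalar vs per-dimension `rand`.** The update rule's notation reads as
  one scalar draw per term per particle, and that is the package default
  (`rand_per_dimension = FALSE`). But a scalar-rand particle moves only
  along the line toward its attractors, which searches a 6-dimensional
  anisotropic space poorly. The choice is genuinely open, so it is a
  flag; `register_volumes()` defaults it to `TRUE` (the common PSO
  formulation), which in our phantom experiments is the difference
  between refining rotations to fractions of a degree and stalling
  several degrees short.
* **Velocity clamp**: $v_{\max} = $ `v_max_fraction` $\times$ range per
  dimension, default 0.5. Initial velocities are drawn uniformly within
  $\pm v_{\max}$.
* **Boundary handling.** Positions are clamped to the search box. Two
  treatments of the accompanying velocity are offered: leave it unchanged
  (the simplest rule, the default for the benchmark protocol) or reflect
  the offending components. With the velocity left unchanged a particle
  pressed outward stays glued to the wall until its velocity happens to
  flip — bounds become absorbing, and registration runs were observed
  converging *exactly at* an angular bound. `register_volumes()` therefore
  uses the reflecting rule. The benchmark surface keeps the plain rule so
  that the comparative protocol (below) is what it documents.
* **Parameter normalization in registration**: the six heterogeneous
  parameters are mapped to $[0, 1]$ internally so one velocity clamp
  governs millimetres and degrees alike.
* **Optimization sense**: the engines maximize; minimization problems are
  negated at the adapter boundary, and all user-facing scores are on the
  objective's own scale.

## The benchmark harness

Four classic test problems validate the optimizers: the 3-d sphere (F1),
the 2-d Rosenbrock valley (F2), the 20-d Rastrigin function (F3,
`200 + sum(x^2 - 10 cos(2 pi x))`), and the 10-d Griewank function (F4,
with the conventional $\cos(x_i/\sqrt{i})$ product term). All have optimum
0 at the origin (F2 at $(1,1)$). A misprinted quartic variant of F2 that
is sometimes seen — linear in $x_2$, with its box minimum on the boundary
rather than at the valley — is kept as `f2_printed()` for fidelity
experiments but never used by the harness; a grid oracle in the tests
verifies the Griewank form is non-negative with its only zero at the
origin.

**Recovery error.** A run's quality is the range-normalized mean squared
error of its best position against the known optimum, in percent:

$$\mathrm{err} = 100 \times \frac{1}{d} \sum_{i=1}^{d}
\left(\frac{\hat{x}_i - x_i^\ast}{u_i - l_i}\right)^2 .$$

Zero when exact, 100 when off by the full range in every coordinate, and
invariant to jointly rescaling bounds and positions. Other error
definitions produce numbers on very different scales, so absolute values
are only comparable within this definition; the *ordering* of methods is
the robust comparison.

**Protocol.** `run_benchmark()` performs $n$ independent runs (default
40) of 100 generations with 56 particles (4 subpopulations for HPSO); run
$r$ seeds the generator with `base_seed + r`, so any run is individually
reproducible. `subpopulation_sweep()` repeats the protocol across island
counts $N$; accuracy characteristically improves from $N = 1$ (plain PSO)
through moderate $N$ and degrades again when islands become too small to
search on their own. The test suite runs the sweep at 560 particles — a
size chosen so the full sweep finishes in minutes while preserving the
non-monotone shape.

## The synthetic multimodal phantom

No external volumes are required: `make_multimodal_pair()` fabricates a
fixed/moving pair with exactly known ground truth on the default
$128 \times 128 \times 15$ grid with $2.59 \times 2.59 \times 8.0$ mm
spacing (tests and the acceptance experiment use $64 \times 64 \times 15$
to keep run times down; the geometry is specified in fractions of the
field of view, so it scales with the grid).

Design of the default geometry, driven by identifiability:

* **Nested eccentric shells with a protruding lobe.** The body is three
  nested ellipsoids at increasing intensity, each inner one *offset*
  within its parent, plus a lobe at body intensity that makes the outer
  silhouette a teardrop. The shells give the interior a radial intensity
  gradient — every voxel, not just boundaries, carries alignment
  information, a stand-in for the texture of real anatomy. The
  eccentricity and the lobe remove rotational symmetry at bulk-mass
  level: without them a 180° in-plane flip of the dominant mass, with a
  compensating translation, is nearly as good as the truth and becomes a
  strong spurious optimum. Even with them, that flipped pose remains a
  genuine local maximum of binned MI (measured roughly 0.25 bits below
  the true pose on the default phantom), and a minority of short
  optimizer runs commit to it — see the limitations below.
* **Two off-body features** — a bright nodule high on one flank and a dark
  box low on the other — break the remaining reflections, and **three
  fiducial-like marker spheres** at long lever arms from the pivot give
  small out-of-plane tilts a sharp metric penalty. Out-of-plane
  information is the scarcest resource on a 15-slice, 8 mm grid, which is
  why the shell offsets include the z axis and the markers span it.
* **Modality maps.** The fixed image is the phantom as-is; the moving
  image is rendered through a piecewise-linear, *non-monotone* intensity
  lookup, so tissue ordering differs between the two "acquisitions" —
  correlation-style metrics fail on such a pair by construction while MI
  does not. Swapping the two maps relabels intensity classes without
  changing shared information, a property the tests check.
* **Analytic rendering.** The moving volume is rasterized by evaluating
  the geometry at the inverse-transformed voxel centers, not by
  resampling the fixed grid. A resampled moving image would carry
  interpolation blur, and the blur is alignment-dependent: it displaces
  the MI optimum away from the true transform. Analytic rendering keeps
  the ground truth exact, as if the simulated object had been scanned in
  the transformed pose.
* **Noise**: additive Gaussian on the moving image, default 1% of the
  dynamic range; the generator's seed drives only this draw, so noise-free
  pairs are fully deterministic.

What the phantom does *not* emulate: anatomical shape variability,
modality-specific noise physics (Rician magnitude noise, CT streaks),
intensity inhomogeneity fields, partial-volume mixtures of more than two
classes, or content that appears in one modality only. Consequently,
passing phantom-recovery tests demonstrates that the optimizer can drive
the MI metric to the correct pose on well-posed multimodal data at this
resolution — not that the pipeline is robust to pathology, field bias, or
occlusion on clinical scans.

## Registration defaults and evaluation

* **Search bounds** (`default_parameter_bounds()`): translations within
  ±half the field of view per axis; in-plane rotation ±180°; out-of-plane
  rotations ±30°. Fully configurable per problem.
* **Protocol**: 56 particles, 4 subpopulations, 100 generations — the
  same budget the benchmark protocol uses; at $64 \times 64 \times 15$
  one registration is roughly 5,700 metric evaluations.
* **Recovery error ("diff")**: per parameter block (translation triple,
  rotation triple), the Euclidean norm of the 3-vector error divided by 3
  (`parameter_diff()`). The test suite verifies this formula reproduces a
  published set of recovery-table diff cells from their printed estimates
  and answers to ±0.005.
* **Landmark error** (`landmark_error()`): the mean displacement, in mm,
  between an estimated and a gold-standard transform over a set of
  fiducial points — the standard external-validation measure when a
  marker-based gold standard exists. It is exercised on synthetic
  landmark sets; no external database ships with the package.

## Numerical details worth knowing

* Best-so-far scores (personal, island, global) are monotone by
  construction; property tests assert every trace.
* The engines evaluate vectorized objectives (attribute
  `vectorized = TRUE`) in one call per island per generation; the
  benchmark functions provide matrix forms, which is what makes 40-run
  protocols and 560-particle sweeps cheap.
* A constant image yields a single-bin histogram with zero entropy; MI
  against anything is then 0, which is correct and does not error.
  An *empty* mask errors — there is nothing to estimate.
* Degenerate inputs are rejected early with messages naming the offending
  quantity: non-finite objective values (with the position), subpopulation
  sizes below 2, zero-width bounds, empty landmark lists, empty phantom
  geometry.
* Reported seeds: every optimizer run reseeds R's generator from its
  control seed, so any reported number is reproducible from its recorded
  configuration alone.

## Known limitations

* Rigid transforms only; no deformable extension, no 2D path.
* Single-resolution metric: no pyramid, no smoothing schedule. On
  low-information axes (few thick slices) the out-of-plane angles are the
  least constrained parameters, and with the fixed 5,700-evaluation
  budget individual runs can stall a few degrees short of the optimum on
  unlucky seeds; batteries of seeds show the median run refining
  rotations to fractions of a degree, while roughly one seed in three
  commits to the half-turn local maximum described above and misses by
  tens of degrees. Verifying a run is cheap — compare its best MI against
  a second seed's — but the default protocol deliberately reports the
  single seeded run as-is.
* The binned MI surface is piecewise-flat at fine parameter scales, which
  bounds achievable precision at roughly the scale where single voxels
  change bins.
* Optimization is serial; the protocol-sized problems used here do not
  warrant process-level parallelism, and determinism per seed was judged
  more valuable.
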