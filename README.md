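# swarmreg

Rigid 3D multimodal image registration driven by a hybrid particle swarm
optimizer, for image-analysis researchers and engineers who need a
derivative-free global optimizer behind a mutual-information metric — and a
reproducible synthetic benchmark to validate it against.

## The problem and the method

Aligning volumes from different acquisition physics (CT to MR, say) defeats
intensity-difference metrics because the two modalities disagree about which
tissue is bright. Mutual information (MI) sidesteps this: with joint
intensity distribution $p_{AB}$ estimated from a discrete joint histogram,

$$\mathrm{MI}(A,B) = H(A) + H(B) - H(A,B), \qquad H = -\sum p \log_2 p,$$

is maximal when one image's intensity classes predict the other's, however
the classes are labeled. Registration is then global optimization of a
rough, multimodal 6-parameter surface — translations $(t_x, t_y, t_z)$ and
Euler angles $(\alpha, \beta, \gamma)$ of the rigid transform
$T(\mathbf{x}) = R(\mathbf{x} - \mathbf{c}) + \mathbf{c} + \mathbf{t}$:

$$\hat{T} = \arg\max_T \mathrm{MI}\left[f_1(\mathbf{x}), f_2(T(\mathbf{x}))\right].$$

The optimizer is a particle swarm with the inertia-weighted update

$$v \leftarrow w v + c_1 r_1 (p_{\text{best}} - x) + c_2 r_2 (g_{\text{best}} - x),
\qquad x \leftarrow x + v,$$

($c_1 = c_2 = 2$, $w$ decreasing linearly 0.98 → 0.4) hybridized with two
genetic-algorithm ingredients: the swarm is split into island
**subpopulations**, each chasing its own best, and once per generation the
two best island leaders produce offspring by **arithmetic crossover**
(complementary convex combinations; speed-preserving velocity
recombination) that replace the worst members of their islands. Islands
preserve diversity on multimodal surfaces; crossover shares information
between the best islands without collapsing them.

The package also ships the supporting cast: a rigid-transform/trilinear
resampling layer with world-space (mm) geometry, NIfTI and MetaImage I/O, a
four-function benchmark harness (sphere, Rosenbrock, 20-d Rastrigin, 10-d
Griewank) with a seeded 40-run protocol, a synthetic multimodal phantom
generator with exactly known ground truth, parameter-recovery ("diff") and
fiducial landmark error measures, and a small CLI
(`inst/cli/swarmreg`).

## Worked example

Generate a noise-free multimodal phantom pair whose ground truth is a 120°
in-plane rotation plus a (20, 10, 2) mm translation, then recover the
transform:

```r
library(swarmreg)

spec <- phantom_spec(size = c(64, 64, 15), noise_sd = 0, seed = 11)
pair <- make_multimodal_pair(
  spec, rigid_transform(angles = c(0, 0, 120), translation = c(20, 10, 2)))

fit <- register_volumes(
  pair$fixed, pair$moving, bins = 64,
  control = swarm_control(n_particles = 56, n_subpopulations = 4,
                          iterations = 100, seed = 1,
                          rand_per_dimension = TRUE, boundary = "reflect"),
  truth = pair$truth)
fit
#> <registration_result> method = HPSO | bins = 64
#>   best MI: 0.67815 bits
#>   translation (mm): 20.273, 9.8137, 0.58708
#>   rotation (deg):   -2.3004e-05, -0.0076886, 120.29
#>   diff vs truth: translation 0.4837 | rotation 0.09652
```

The reported `diff` values are the per-block recovery errors
`‖estimate − truth‖₂ / 3` — here the rotation is recovered to 0.10° and the
translation to 0.48 (mm units), from a search box spanning ±half the field
of view in translation and ±180° in-plane. `tidy(fit)` returns the
per-generation MI trace, `glance(fit)` the one-row summary,
`autoplot(fit)` the convergence plot.

The same machinery validates the optimizer on analytic test functions:

```r
bench <- run_benchmark("F3", "hpso",
                       swarm_control(n_particles = 56, n_subpopulations = 4,
                                     iterations = 100),
                       n_runs = 40, base_seed = 0)
bench
#> <benchmark_result> F3 | HPSO | 40 runs
#>   mean relative error: 0.9972 %
```

— the mean over 40 seeded runs of the range-normalized squared recovery
error (in percent) of the best position against the known optimum of the
20-parameter Rastrigin function.

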