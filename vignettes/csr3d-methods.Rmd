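---
title: "Testing complete spatial randomness on convex 3D surfaces: models and methods"
author: "csr3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing complete spatial randomness on convex 3D surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csr3d)
```

## The problem

Modern 3D super-resolution microscopy returns point patterns of molecules on
the membranes of cells — surfaces that are closed, bounded and convex but
rarely spherical (bacteria are better described by ellipsoids). The first
question asked of such a pattern is whether it is *completely spatially
random* (CSR): a homogeneous Poisson process on the surface, with constant
intensity and independent counts. The classical toolkit (Ripley's K, the
empty-space F, the nearest-neighbour H, and their ratio J) is built on
stationarity or isotropy, and an arbitrary convex surface has essentially no
isometries, so none of those functions can even be defined there directly.

`csr3d` implements the mapping route around this obstruction. A Poisson
process pushed through a measurable bijection is again a Poisson process, so
a pattern on a centred convex surface $D$ can be mapped to the unit sphere
$\mathbb S^2$ — radially, $f(x) = x/\lVert x\rVert$, or for ellipsoids by
axis scaling $f(x) = (x_1/a, x_2/b, x_3/c)$ — where the full rotation group
is available and *inhomogeneous* summary statistics are well defined. The
price is that a homogeneous process on $D$ becomes an inhomogeneous Poisson
process on the sphere, with an intensity $\rho^*$ determined by the geometry
of $D$; the gain is that $\rho^*$ is known exactly.

## Geometry: shapes, area elements, geodesics

A `convex_shape` is a level set $g(x) = 0$ partitioned into pieces on which
one coordinate is a single-valued height function $\tilde g_i(x_1, x_2)$ of
the other two; surface integrals reduce to planar integrals against the
area element $l_i(u) = \sqrt{1 + |\nabla \tilde g_i|^2}$. Spheres,
ellipsoids and cubes are built in (`cs_sphere()`, `cs_ellipsoid()`,
`cs_cube()`); spheres and spheroids also carry closed-form areas, checked
against piecewise quadrature (a $\sin\psi$ substitution removes the
integrable rim singularity of $l$ on curved pieces).

Geodesic distances are exact great circles on spheres. On ellipsoids no
closed form exists; the package uses a subdivided icosahedral mesh
(default 5 subdivisions, 10\,242 vertices) whose distance graph contains
the mesh edges plus chord shortcuts to each vertex's second and third
lattice rings. The shortcuts raise the number of available path directions
from 6 to roughly 24, which cuts the metrication overshoot of pure edge
paths from about 15% to under 2%. Query points are snapped to their nearest
vertex and the snap is removed to first order by projecting the chord
direction into the tangent plane (the gradient of geodesic distance is the
geodesic's unit tangent); separations under 2.5 edge lengths use the chord
directly. Measured against the great-circle oracle on a sphere-shaped
ellipsoid, the absolute error stays below about 0.01 length units (a
quarter edge) and the relative error below ~1% beyond a few edge lengths;
on strongly elongated spheroids the local mesh edge — and with it the error
budget — scales with the longest semi-axis. Geodesic ball areas
$\lambda_D(B_D(x,r))$ sum per-vertex Voronoi-style areas (normalised so
they total the exact surface area) inside the mesh ball, and are exact
spherical caps $2\pi(1-\cos r)$ on spheres.

## The mapped intensity

For the radial map the intensity transform factors as
$$\rho^*(y) \;=\; \rho(x)\, l_i(u)\, \frac{du}{dy}\,
\sqrt{1 - y_{i_1}^2 - y_{i_2}^2},$$
where $u$ are the planar coordinates of $x = f^{-1}(y)$ on its piece,
$du/dy$ is the inverse Jacobian determinant of the planar map induced by
the projection, and the square root converts planar measure on the image
disc back to spherical surface measure. On the cube with half-side 1 this
collapses to $\rho^*(y) = \rho\,(1 - y_1^2 - y_2^2)^{-3/2}$ on each face
image (in that face's planar axes), with infimum $\rho$ at the face-centre
images. For an ellipsoid under axis scaling,
$$\rho^*(y) = \rho\, a b \sqrt{1 - (1 - c^2/a^2)\,y_1^2
                                 - (1 - c^2/b^2)\,y_2^2},$$
with infimum $\rho a b$ at the poles for prolate shapes. Two properties
arbitrate the implementation and are enforced in the tests: the intensity
measure is conserved, $\int_{\mathbb S^2} \rho^* = \rho\,\lambda_D(D)$, and
binned counts of mapped CSR patterns are Poisson with means
$\int_{\rm bin}\rho^*$. Both maps are exactly invertible; piece-boundary
points resolve to the lowest-index piece so results are deterministic.

```{r mapped-intensity}
ell <- cs_ellipsoid(1, 1, 3)
mapped_intensity(ell, rbind(c(0, 0, 1), c(1, 0, 0)), rho = 5)
rho_star_inf(ell, 5)
```

## Estimators on the sphere

With $Y$ the mapped pattern, $\bar\rho^* = \inf \rho^*$, and
$A_r = 2\pi(1 - \cos r)$ the cap area, the package computes

* `Kinhom`: $\hat K(r) = \frac{1}{4\pi}\sum_{x \neq y}
  \mathbf 1[d(x,y) \le r]/(\rho^*(x)\rho^*(y))$, unbiased for $A_r$;
* `Finhom`: $1 - \frac{1}{|P|}\sum_{p \in P} \prod_{x \in Y \cap B(p,r)}
  (1 - \bar\rho^*/\rho^*(x))$ over a reference grid $P$, unbiased for
  $1 - e^{-\bar\rho^* A_r}$;
* `Hinhom`: the same product referenced at the events (ratio-unbiased);
* `Jinhom` $= (1-\hat H)/(1-\hat F)$, identically 1 for Poisson processes;
  radii where $\hat F = 1$ are flagged `NA`, never clamped;
* `Ktilde`: the unknown-rate version
  $\tilde K(r) = \frac{\lambda_D^2(D)}{4\pi N(N-1)} \sum_{x\neq y}
  \mathbf 1[d \le r]/(\tilde\rho(x)\tilde\rho(y))$ with
  $\tilde\rho = \rho^*/\rho$ a pure geometry factor, and the zero curve for
  $N \le 1$;
* `Pinhom`: $\sqrt{K(r)} - \sqrt{A_r}$, the variance-stabilised centred
  transform (zero in mean under CSR); the untransformed difference is
  exposed separately as `Kcentred`.

The reference grid $P$ is a spherical Fibonacci lattice (default
$|P| = 256$); exact equidistribution on the sphere is impossible for
general $n$, and the F-estimator's properties hold for any fixed grid.
Pairwise distances use clipped `acos` of dot products; the empty pattern's
H is defined as the zero curve and flagged. The default radius grid is
$\{0, 0.02, \dots, \pi\}$, matching the reference simulation study.

## Exact moments

For Poisson processes with known intensity the package provides exact
means, variances and the H–F covariance (`theo_mean_*`, `var_K`, `var_F`,
`var_H`, `cov_HF`). These were derived via the Mecke formula with
$1/(N+k)$ handled through $\int_0^1 t^{N+k-1}\,dt$; the resulting helper
integrals are evaluated in numerically guarded forms (the exponential
integral appears through
$\int_0^1 (-\ln t)e^{at}dt = (\mathrm{Ei}(a) - \ln a - \gamma)/a$, with an
asymptotic branch beyond $a = 50$ so the $e^{-\mu}$ prefactor can be
absorbed before overflow). Constant intensities use rotationally reduced
1D integrals (cap-intersection areas by quadrature, splined over the
separation angle); functional intensities use exact cap quadrature for
smooth integrands and Fibonacci pair sums (documented ~1% accuracy) for
the indicator-based double integrals.

One caution surfaced during verification: the exact small-count bias of
$\hat H$ implied by its expectation is
$(a e^{-a} - \mu e^{-\mu})/(\mu - a)$ with $a = \bar\rho A_r$ — of order
$(a/\mu)e^{-a}$, not of order $e^{-\mu}$. It is negligible at the study's
event counts but not astronomically so; the tests therefore check $\hat H$
against its exact mean rather than against an $e^{-\mu}$ bound.

The delta-method moments of $\hat J$ (`j_moments`) plug the exact moments
into the second-order Taylor expansion of a ratio. The expansion is only
meaningful where the empty-ball probability $e^{-\bar\rho A_r}$ is not
minuscule; outside that range (and always for constant intensity, where
the formal existence radius `j_rmax` is zero) a warning is issued.
$\hat J$ itself is heavy-tailed, so its empirical mean converges slowly;
the expansion carries $O(\mathrm{CV}^3)$ truncation error.

For the unknown-rate $\tilde K$ the bias is $-P(N \le 1) A_r$ and the
variance decomposes into a small-count block
$4\pi^2(1-\cos r)^2 (1-P_1)P_1$, a triple-correlation block driven by
$I_1 = \int 1/\tilde\rho$, and a pair block driven by
$I_2(r) = \iint \mathbf 1[d \le r]/(\tilde\rho\tilde\rho)$, weighted by
the Poisson expectations $E[(N+3)^{-2}(N+2)^{-2}]$ and
$E[(N+2)^{-2}(N+1)^{-2}]$ (series truncated at 12 standard deviations,
truncation error $<10^{-12}$). The plug-in estimator
(`estimate_var_Ktilde`) substitutes falling-factorial estimators
$\hat\rho^k = N(N-1)\cdots(N-k+1)/\lambda_D^k$, the observed shifted-count
values, and a ratio-unbiased estimator of $(1-P_1)P_1$ assembled from
$R(N,k,p) = N!\,e^{N-k}/((N-k)!\,(e+p)^N)$; negative values (possible at
small $N$) are floored at zero. The geometry integrals $I_1, I_2$ reduce
to 1D/2D quadratures for spheroids and are cached per shape.

## Simulators

* `rpois_shape`: $N \sim \mathrm{Poisson}(\rho\,\lambda_D(D))$, points
  i.i.d. uniform (or proportional to a supplied intensity, by thinning).
  Uniform sampling on spheroids rejects unit-sphere directions against the
  exact area-element weight $abc\sqrt{u_1^2/a^2+u_2^2/b^2+u_3^2/c^2}$,
  whose envelope is finite (the per-piece height-function scheme is not
  usable there: its area element is unbounded at the rim). Cube faces are
  flat and sampled directly.
* `rmatern1_shape` / `rmatern2_shape`: hard-core thinning in the surface's
  geodesic metric — delete every event with a neighbour within $R$
  (type I), or only if that neighbour carries a smaller independent mark
  (type II; default marks exponential with rate 1, ties broken by index
  order). `solve_matern2_intensity` inverts the expected-count equation
  $\int_D (1 - e^{-\rho \lambda_D(B_D(x,R))})/\lambda_D(B_D(x,R))\,
  d\lambda_D(x) = \mu$ — closed form on spheres, ball-area quadrature plus
  a bracketing root-finder elsewhere — and reports the attainable maximum
  when the target is infeasible.
* `rthomas_shape`: Neyman–Scott clustering. Parents are homogeneous
  Poisson and are *not* part of the output; each spawns
  $\mathrm{Poisson}(\alpha)$ offspring from a Riemannian Gaussian kernel
  $k(x,c) \propto e^{-d^2(x,c)/2\kappa^2}$ in geodesic distance (the
  normaliser $\chi$ reduces to a 1D integral on spheres and to mesh
  quadrature elsewhere). Offspring are drawn by rejection from uniform
  proposals with envelope 1 on the unnormalised kernel; proposals are
  chord-pre-filtered beyond $6\kappa$, where the kernel is below
  $e^{-18}$. $\kappa = \infty$ gives CSR with intensity
  $\rho_{\rm parent}\alpha$.

All simulators are bit-reproducible under a seed; experiment repetitions
derive per-repetition seeds from a root seed by a fixed affine map
(`derive_seed`), so runs replay exactly and parallelise by row.

## The CSR test

The test statistics are computed on the discrete grid
$R = \{0, 0.02, \dots, \pi\}$:
$$T_1 = \max_r \bigl|\sqrt{\tilde K(r)} - \sqrt{A_r}\bigr|, \qquad
  T_2 = \max_r \frac{|\tilde K(r) - A_r|}
               {\sqrt{\widehat{\mathrm{Var}}(\tilde K(r))}},$$
with radii whose variance estimate is zero (always $r = 0$) contributing 0
to $T_2$. `mc_test` computes the observed statistic and $m$ null statistics
from CSR simulations and returns the add-one Monte-Carlo p-value
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(m+1)$ — exact for
exchangeable statistics, with ties counted conservatively. The test is
one-sided in the absolute deviation, as in the reference study.

Two null-intensity conventions exist and they matter for $T_1$. For data
analysis (`mc_test`, `csr_envelope`) the null rate is fitted from the
observed count, $\hat\rho = N/\lambda_D(D)$ — the only option when the
true rate is unknown. For the simulation study (`run_experiment`) the
default null uses the design intensity: with fitted nulls the extra
Poisson variability of the null counts inflates the right tail of the
*unstandardised* $T_1$, making its empirical level ~0.005 instead of 0.05
($T_2$ standardises per count and is immune); the reference study's own
CSR rows (0.039–0.056) are only consistent with exchangeable nulls. The
fitted variant remains available via `null = "fitted"`.

`csr_envelope` returns pointwise min/max envelopes over $m$ fitted-null
curves for any of the summary statistics, with observed and theoretical
curves, and a base-graphics `plot` method shading the envelope.

## The simulation study at desk scale

`experiment_config`/`run_experiment` reproduce the calibration and power
study: prolate spheroids with $a = b \in \{1, 0.8, 0.6, 0.4\}$ and $c$
solved so the area is exactly $4\pi$ (`solve_c_for_area`; at $a = 0.8$ the
root is $c = 1.43981$), CSR rows at expectation $40\pi$, hard-core rows at
expectation 100 with the thinning intensity from the expected-count
equation, cluster rows at expectation 150 with 20 offspring per parent.
The default reproduction scale is 200 repetitions against 199 nulls per
test (the full-scale study used 1000 and 999; rates at the reproduction
scale carry binomial standard errors of 0.015–0.035, which is also the
scale used in the acceptance suite). A single CSR row at the default scale
runs in about a minute on one core; the test suite's moment gates use
1000–5000 simulations per check.

## What the synthetic data do and do not show

The generators emulate the study conditions exactly: known convex shapes,
constant (or designed) intensities, independent repetitions. Passing tests
demonstrate correctness of the estimators, moments and test calibration
under those conditions. Real membrane data differ in ways the suite cannot
certify: the surface itself is estimated (segmentation error), the true
shape is only approximately ellipsoidal, localisation noise displaces
events off the surface, and intensities may vary for biological reasons —
rejection of CSR then indicates *some* departure, not specifically
clustering or inhibition. Nonparametric estimation of $\rho^*$ from data
is deliberately out of scope.

## Known limitations

* Cube support covers CSR simulation, mapping and summaries only; cube
  geodesics (unfolding) are not implemented, so hard-core and cluster
  models are restricted to spheres and ellipsoids.
* Mesh geodesics are approximate (see above); hard-core constraints are
  enforced, and checked, in the same mesh metric.
* The delta-method J moments degrade where empty-ball probabilities are
  tiny; use the envelope machinery for J-based diagnostics instead.
* Non-convex or open surfaces, and piecewise-planar approximations of
  arbitrary shapes, are out of scope.
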