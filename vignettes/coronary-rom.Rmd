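---
title: "Reduced-order reconstruction of coronary pressure and wall shear stress"
author: "coropod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order reconstruction of coronary pressure and wall shear stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coropod)
```

## The problem and the method

Disturbed wall shear stress (WSS) and pressure gradients are strong
predictors of where atherosclerotic plaques form, progress and rupture,
but the 3-D computational fluid dynamics (CFD) needed to compute them is
far too slow for use during a catheterisation. `coropod` implements a
physics-based machine-learning shortcut: learn, once and offline, how the
steady pressure and WSS fields of a family of coronary-artery-like
vessels vary with vessel shape, and then reconstruct the fields of a new
vessel in a fraction of a second without any flow solve.

The pipeline has five stages:

1. **Synthetic phantoms.** A set of reference vessels is perturbed by a
   randomised composite of two sinusoids applied to the radius profile,
   giving a large ensemble of smoothly varying shapes on a single frozen
   mesh topology.
2. **Flow surrogate.** Each phantom is solved with a quasi-1D steady
   generalized-Newtonian (Carreau-Yasuda) tube-flow model, producing a
   pressure value per volume node and a WSS value per surface node.
3. **Common-base POD (cPOD).** The per-mesh field vectors are stacked
   into an `M x N` solution matrix and factored by SVD,
   `A = U D V^T`. Because all meshes share one node basis, the rows of
   `V^T` are spatial modes common to the whole ensemble and the rows of
   `U D` are each mesh's principal coefficients. Ten modes suffice to
   represent either field with sub-percent reconstruction error.
4. **Shape embedding.** Each mesh's centroid-centered node-coordinate
   vector is embedded in 2-D with t-SNE; unseen meshes are placed in the
   same plane by nearest-neighbour kernel interpolation.
5. **Coefficient regression.** A chain of random forests maps the 2-D
   embedding coordinates to the ten POD coefficients per field; combining
   predicted coefficients with the stored modes reconstructs the fields.

The package's default configuration is the study design it is built
around: 7 references x 200 perturbations + 7 originals = 1407 meshes,
10 retained modes per field, an 80/20 shuffled train/validation split,
and forests of 70 trees with maximum depth 20.

## Synthetic geometry

A reference vessel is a straight tube of length 30 mm and mean radius
1.5 mm whose baseline radius profile carries a fixed low-frequency cosine
modulation, with a distinct amplitude (0.04–0.16) and frequency (0.5–1.4
cycles per length) per reference. Real reference anatomies would come
from intravascular imaging; the synthetic family reproduces the property
the pipeline actually depends on — several geometrically distinct parents,
each surrounded by a cloud of small smooth perturbations — without any
patient data.

Phantoms modulate the baseline as

$$r(s) = r_0(s)\,\Big(1 + \sum_{j=1}^{2}\big[a_j \sin(2\pi f_j s/L + \varphi_j) + d_j\big]\Big),$$

with amplitudes $|a_j| \le 0.08$, offsets $|d_j| \le 0.03$, frequencies
$f_j \in [0.5, 2.5]$ cycles per length and free phases. The bounds are a
deliberate compromise: large enough that the induced field changes are
significant (pressure responds roughly like $r^{-4}$, so an 11% radius
deviation moves the pressure drop by tens of percent), small enough that
the worst-case bracket $1 - 2(a_{\max}+d_{\max}) = 0.78$ keeps every
radius positive and the solution ensemble low-rank. The sup-norm radius
deviation is bounded by $\sum_j(|a_j|+|d_j|)$, which the test suite
verifies on dense station grids.

Meshing is a structured tube grid with frozen ordering (station-major,
then ring — axis node first, interior rings inside out — then angle):
`Ns = n_ax * n_circ` surface nodes and `Nv = n_ax * (n_rad*n_circ + 1)`
volume nodes. At the default resolution (101 stations, 32 circumferential
points, 4 interior rings) that is 3,232 surface and 13,029 volume nodes,
preserving the strong surface/volume imbalance of realistic CFD meshes
(about 1:4 here). The centerline is straight; curvature, torsion and side
branches are out of scope.

```{r geometry-example}
refs <- reference_vessels(n = 2, n_ax = 21, n_circ = 8, n_rad = 2)
ds <- generate_dataset(refs, n_perturb = 3, seed = 1)
ds
head(dataset_params(ds), 3)
```

## The flow surrogate

The full problem would be a 3-D steady incompressible Navier–Stokes solve
per phantom. The package deliberately replaces it with a quasi-1D
generalized-Newtonian model so the whole study runs on a desktop in
seconds while preserving what the reduced-order stages rely on: a smooth,
deterministic dependence of the fields on the geometry.

Per station the model applies fully developed tube-flow relations to the
local radius:

* flow rate $Q = U_{in}\,\pi r(0)^2$ conserved exactly (inlet speed
  100 cm/s, a typical coronary value);
* Poiseuille wall shear rate $\dot\gamma_w = 4Q/(\pi r^3)$;
* Carreau–Yasuda kinematic viscosity
  $\nu = \nu_\infty + (\nu_0-\nu_\infty)\big(1+(\tau\dot\gamma)^\alpha\big)^{(n-1)/\alpha}$
  with the standard blood coefficients $\nu_\infty = 3.45\times10^{-6}$,
  $\nu_0 = 56\times10^{-6}$ m²/s, $\tau = 3.313$ s, $\alpha = 2$,
  $n = 0.3568$ — blood shear-thins by an order of magnitude between rest
  and arterial shear rates;
* wall shear stress $\tau_w = \rho\,\nu(\dot\gamma_w)\,\dot\gamma_w$
  (density 1060 kg/m³ converts the kinematic model to stresses in Pa);
* pressure from the axial force balance $dp/ds = -2\tau_w/r$, integrated
  upstream from the zero-pressure outlet with the trapezoidal rule and
  assigned uniformly across each station's volume nodes.

In the Newtonian limit ($\nu_0 = \nu_\infty$) the model collapses to the
closed-form Poiseuille drop $\Delta p = 8\rho\nu L Q/(\pi r^4)$, which the
suite checks to 0.1% on a uniform tube. What the surrogate does *not*
attempt: turbulence (the target vessels sit at transitional Reynolds
numbers where a RANS closure would be used in full CFD), radial pressure
variation, flow separation downstream of stenoses, entrance effects,
pulsatility, or wall compliance. The solver sits behind a registry
(`register_solver()`), so a full CFD backend honouring the same
`vessel_geometry -> flow_solution` contract can be swapped in without
touching the downstream stages.

```{r solver-example}
sol <- solve_flow(ds[[1]])
sol
kinematic_viscosity(c(0, 1, 100, 1e4)) * 1e6   # in 1e-6 m^2/s
```

## Common-base POD

Two conventions matter and are fixed deliberately:

* **No mean-centering by default.** The stacked solution matrix is
  factored directly, so mode 1 carries the ensemble-mean field pattern
  and the ensemble mean needs no separate bookkeeping at prediction time.
  Centering is available (`center = TRUE`) but off by default.
* **Energy is the singular-value sum.** Truncation uses
  $\sum_{i\le k}\sigma_i / \sum_i \sigma_i$, treating the singular values
  themselves as the information content. This is more conservative than
  the variance (squared) fraction, which `energy_fraction(..., squared =
  TRUE)` also reports for comparison.

The factorisation itself has two routes: the direct LAPACK SVD, and the
snapshot method via the `M x M` correlation matrix `A A^T`, selected
automatically when the node count exceeds four times the mesh count (at
the default scale the matrices are 1407 x 13,029 and 1407 x 3,232, so the
snapshot route is the economical one). The two routes agree on singular
values and coefficients to numerical precision; a sign convention (the
largest-magnitude entry of every mode is non-negative) makes the modes
reproducible across backends. Modes are retained down to a relative
singular-value tolerance of `1e-10`; the trailing numerically null
directions are dropped from the mode set but the full spectrum is kept
for energy accounting. On the default ensemble the ten leading modes
carry more than 99% of singular-value energy for both fields and the
mean range-normalised 10-mode reconstruction RMSE is about 0.006%
(pressure) and 0.08% (WSS) — comfortably below the 1% / 5% retention
bounds the pipeline is designed to.

```{r pod-example}
sols <- lapply(ds, solve_flow)
A <- assemble_solution_matrix(sols, "pressure")
basis <- pod_decompose(A)
round(100 * vapply(1:4, energy_fraction, 0, basis = basis), 2)
```

## Shape embedding

No t-SNE implementation ships with the R environments this package
targets, so `tsne_embed()` provides a self-contained exact
(dense, O(M²)) implementation of the standard algorithm: per-point
Gaussian bandwidths calibrated to the target perplexity by bisecting the
Shannon entropy, then momentum gradient descent on the KL divergence to
the Student-t map affinities, with early exaggeration and adaptive gains.
Exact t-SNE is entirely adequate at ensemble sizes of a few thousand; a
Barnes–Hut approximation would only matter at much larger M.

Choices worth noting:

* **Perplexity defaults to 30** and is exposed, not auto-tuned. At the
  default M = 1407 this gives an approximately homogeneous point cloud
  that still resolves one cluster per reference parent; the test suite
  checks the cluster property (mean intra-parent distance below mean
  inter-parent distance) on a reduced 7-parent ensemble.
* **Shapes are centroid-centered but not scale-normalised** before
  flattening: overall vessel calibre is physically informative (the
  fields scale strongly with radius), so it must survive into the
  embedding distances.
* **Out-of-sample placement** is the package's own deterministic rule:
  the 2-D position of an unseen mesh is the Gaussian-kernel-weighted mean
  of its `k_nn = 5` nearest training embeddings, with bandwidth equal to
  the median neighbour distance, and an exact shape match returns the
  training coordinate itself. t-SNE has no native out-of-sample map, and
  this interpolation is exact on training data, continuous in the query,
  and cheap.
* The embedding is 2-D; higher-dimensional embeddings trade sparser
  feature spaces for cluster fidelity and are not explored here.

## Coefficient regression

Each field gets a chain of `ranger` random forests (70 trees, maximum
depth 20): forest *j* regresses coefficient *j* on the two embedding
coordinates plus the chain's predictions for coefficients 1..j-1,
ordered by descending singular value so the dominant modes are predicted
first. During fitting the downstream forests consume the chain's own
training-set predictions for upstream modes — the same quantities they
will see at prediction time — rather than the true coefficients; both
variants are implemented (`chain_config(upstream = "true")`) and the
predicted-upstream variant is the default. Forests are seeded per
position in the chain, so fitting and prediction are fully deterministic.

The train/validation split is a seeded 80/20 shuffle. Because a single
shuffle at moderate M leaves visible split-to-split variance,
`split_repeat_metrics()` repeats the split/fit/score cycle (ten repeats
by default) and averages the dominant-mode coefficient RMSE and the
field errors. Coefficient prediction RMSE is normalised by the
training-set range of the corresponding coefficient — held-out predictions
are scored against the spread the model was actually trained on.
`chain_order_check()` reports the same metrics for the reversed chain
order as a diagnostic; order sensitivity is logged, not asserted.

## Evaluation

Field errors follow the range-normalised definitions

$$\mathrm{NMAE}_i = \frac{\sum_j |f^{ML}_{ij}-f^{GT}_{ij}|}{N\,(\max f - \min f)}\cdot 100\%,\qquad
\mathrm{NRMSE}_i = \frac{\sqrt{\sum_j (f^{ML}_{ij}-f^{GT}_{ij})^2/N}}{\max f - \min f}\cdot 100\%,$$

with the normalising range taken over **all** node values of **all**
meshes of the full dataset (training and test together), per field.
Per-mesh errors are aggregated as mean ± standard deviation. Two
structural facts are asserted throughout the suite: NMAE never exceeds
NRMSE (Jensen), and the end-to-end prediction error of any mesh can never
fall below its own truncation error, because the regression error lives
inside the mode span and is orthogonal to the truncation residual.

## Numerical choices and degenerate inputs

* Perturbation parameters outside their bounds, or driving any station
  radius non-positive, are rejected rather than clipped.
* Snapshot eigenvalues are clamped at zero before taking square roots;
  modes are only formed for singular values above `1e-10` of the largest.
* Constant regression targets and single-sample training sets fall back
  to exact constant predictors (a forest would return the mean anyway,
  at more cost).
* A zero coefficient range makes the normalised coefficient RMSE
  undefined; it is reported as `NA` with a warning, never silently 0.
* Single-mesh error reports define the standard deviation as 0.
* Stage seeds derive from the master seed as
  `(seed * 8191 + offset) mod (2^31 - 1)` with documented per-stage
  offsets, so any stage can be rerun in isolation with the seed the full
  run would have used.

## What the synthetic study does and does not show

The generator and surrogate reproduce the *structure* of a real
CFD-based study — seven distinct parents, two hundred smooth small
perturbations each, smooth geometry-to-field maps, a strongly low-rank
solution ensemble, surface/volume node imbalance — and the pipeline's
claims are verified against that structure: dataset counts, viscosity
limits, >95% ten-mode energy retention, sub-percent truncation error,
split reproducibility. What passing these tests does **not** show is
predictive accuracy on real arteries: patient-derived geometries carry
curvature, branching, non-smooth lumen variation and imaging noise, and
a 3-D RANS solve responds to them in ways a quasi-1D model cannot. The
quantitative held-out errors reported on synthetic runs are therefore
properties of this surrogate ensemble, not clinical claims; the solver
registry is the intended seam for substituting real CFD data.

The test suite runs everything at reduced scale (coarse meshes of
21 stations, ensembles of a dozen to ~80 meshes for the embedding and
regression stages) and exercises the full default 1407-mesh ensemble
only for the dataset-structure, energy-retention and truncation-error
checks, where profile-only geometries keep the cost to seconds.

## Limitations

Steady flow only (no pulsatility; a quasi-steady rescaling would be the
natural extension), rigid walls (no fluid–structure interaction),
straight unbranched centerlines, a shear-rate closure that ignores the
velocity-profile shape change of shear-thinning fluids, and a fixed mesh
topology shared by construction rather than by registration. Gaussian
processes would add the uncertainty quantification the forests lack.
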