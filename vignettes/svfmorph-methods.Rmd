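---
title: "Longitudinal morphometry with stationary velocity fields: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal morphometry with stationary velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in **svfmorph**, the numerical
choices behind them, the parameters that matter, and what the synthetic
validation cohorts do and do not establish about behaviour on real imaging
data.

## The model of anatomical change

Within-subject anatomical change between a baseline image $I_0$ and a
follow-up image $I_1$ is represented by a *stationary velocity field* (SVF)
$v$: a time-constant 3D vector field whose flow for unit time defines a
diffeomorphic deformation through the exponential map $\varphi = \exp(v)$.
The SVF is estimated by symmetric LogDemons registration, which minimizes the
symmetric dissimilarity

$$
\| F - M \circ \exp(v) \|^2 + \| M - F \circ \exp(-v) \|^2 + \mathrm{Reg}(v; \sigma),
$$

where the regularizer is Gaussian smoothing of $v$ with standard deviation
$\sigma$. The one-parameter subgroup property
$\exp(v t)\,\exp(v s) = \exp(v (t+s))$ makes half-way images and doubled
deformations exact operations on the field, which the parallel-transport
construction exploits.

Because SVFs estimated in different subjects live in different coordinate
systems, each subject's longitudinal SVF is *normalized* into a common
template space with a single-rung, image-domain Schild's Ladder: register the
template $T_0$ to the subject follow-up, form the half-space image
$P = T_0 \circ \exp(\tfrac12 v)$, register the subject baseline to $P$, form
the template-space follow-up $T_1 = I_0 \circ \exp(2 v_{I_0 \to P})$, and
finally register $T_0$ to $T_1$. The result $v_{\mathrm{norm}}$ expresses the
subject's within-subject change in the template frame. The doubled rung is
realized as $\exp(2v)$, exact for stationary fields; deformation-level
self-composition is available behind a flag and agrees to within a quarter
voxel on the validation fixture, but adds one interpolation pass.

Downstream, the normalized SVF supports two analyses:

* **Classification** of converters (MCIc) versus stable subjects (MCIs) from
  voxelwise features — the SVF components themselves, the Jacobian
  determinant and divergence (local volume change), the geodesic length
  (trajectory length of each particle), and the displacement of
  $\exp(v)$ — z-scored per voxel across subjects, decimated by 4 per axis,
  masked, reduced by kernel PCA, and fed to a linear soft-margin SVM under
  stratified 10-fold cross-validation with a nested grid search over the
  hinge trade-off $c \in \{10^{-3},\dots,10^{3}\}$.
* **Group localization** by a voxelwise two-sample Hotelling $T^2$ test on
  the 3-vector SVF observations, with Benjamini–Yekutieli FDR correction
  (valid under arbitrary dependence) and thresholding at $q \le 0.001$.

## Numerical design

**Units and grids.** Displacements and velocities are stored in voxel units
on an assumed near-isotropic grid. Spacing metadata is carried through I/O
but not used inside derivative operators; this keeps every operator simple
and exactly testable against closed forms.

**Exponential map.** Scaling and squaring with automatic step count: $v t$
is scaled by $2^{-K}$ with $K$ the smallest integer bringing the maximum
displacement under half a voxel, converted to a near-identity deformation by
the second-order flow expansion $u = w + \tfrac12 (Dw) w$, then self-composed
$K$ times. The second-order start matters: with the bare Euler start the
error against a dense matrix-exponential oracle on linear-generator fields is
about $10^{-2}$ voxels; with it, below $10^{-4}$.

**Interpolation and boundaries.** Trilinear interpolation everywhere, with
clamp-to-edge lookups; derivatives are central differences with one-sided
stencils on boundary faces; field smoothing is separable Gaussian
convolution with edge replication (constants are preserved exactly). The
Gaussian kernel is truncated at $4\sigma$.

**Demons force.** The update is the ESM-style symmetric force: the forward
term $u_+ = (F - M_w)\,J / (|J|^2 + \alpha^2 (F - M_w)^2)$ with $J$ the mean
of $\nabla F$ and $\nabla M_w$ and $\alpha^2 = 1$ on pair-normalized
intensities, combined with the analogous backward term as $u_+ - u_-$. The
summed combination (rather than the mean of the two forces) keeps the
per-direction ESM step size; with the halved step the optimizer plateaus
measurably short of the recoverable warp at the default iteration budget
(0.6–0.7 voxel mean endpoint error versus 0.3–0.45). Per-voxel update
magnitude is capped at `max_step` (2 voxels). The update is fluid-smoothed
(`force_sigma`, default 1 voxel), composed into the SVF by second-order BCH
($v + u + \tfrac12[v,u]$, bracket by central differences), and the SVF is
diffusion-smoothed with $\sigma$.

**Multi-resolution.** Smooth-then-subsample pyramid with factor 2, default
three levels with 15/10/5 iterations coarse to fine; the SVF is upsampled
trilinearly between levels with values doubled (voxel units). Levels whose
coarsest grid would fall below 8 voxels per axis are dropped with a warning.
Smoothing parameters are interpreted in the voxel units of each level.

**Key tunables.**

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 1.5 | voxels | diffusion regularization of the SVF; 0 disables it and may yield non-diffeomorphic maps (reported via the minimum Jacobian determinant) |
| `iterations` | 15/10/5 | – | per-level optimizer budget, coarse to fine |
| `force_sigma` | 1.0 | voxels | fluid smoothing of each update |
| `max_step` | 2.0 | voxels | per-iteration displacement cap; guards monotone similarity |
| `bch_order` | 2 | – | order of the update composition |
| `downsample` | 4 | – | feature decimation per axis (nearest neighbour, offset 0) |
| `theta` | `"median"` | feature units | Gaussian KPCA width; see below |
| `folds` | 10 | – | outer cross-validation folds (inner grid search uses 5) |
| `alpha` | 0.001 | – | FDR threshold on BY-corrected q-values |

**Gaussian kernel width.** On $D_2$-dimensional z-scored features, pairwise
squared distances concentrate around $2 D_2 \gg 1$, so a fixed width
$\theta = 1$ drives the kernel to the identity matrix — after centering
there is no usable geometry and out-of-sample projections collapse toward a
constant. `kpca_fit()` therefore accepts `theta = "median"` (the median
heuristic: the median pairwise training distance), which the pipeline uses
by default; a fixed numeric $\theta$ remains available.

**KPCA dimensionality.** All components with centered-kernel eigenvalue
above $10^{-10}$ are kept (at most $N-1$); with the linear kernel the
projections then equal direct PCA scores up to per-component sign, which is
the equivalence the tests assert.

**SVM.** The objective $\|w\|^2 + c \sum_i \max(0, 1 - y_i(\langle w, f_i
\rangle + b))$ with unpenalized bias is solved in the dual by SMO with
maximal-violating-pair selection (C++ inner loop) to a $10^{-8}$ KKT gap;
this equals the standard C-SVM with $C = c/2$. Tests pin the solution
against a projected-subgradient reference and against the installed libsvm
solver. Converters (`MCIc`) are the positive class; AUC uses midranks, so
all-tied decision values give 0.5.

**Leakage control.** Everything fold-dependent — z-score statistics, the
KPCA basis, the inner 5-fold selection of $c$ — is fit on the training part
of each outer fold only. A test reconstructs each fold's model from the
training rows alone and reproduces the held-out decision values to
$10^{-10}$.

**Hotelling $T^2$.** Per voxel, $T^2 = \frac{n_1 n_2}{n_1+n_2} \bar d^\top
S_p^{-1} \bar d$ with pooled covariance $S_p$, transformed to
$F(3, n_1+n_2-4)$. The $3\times3$ solves are closed-form adjugates
vectorized across voxels; near-singular $S_p$ receives a ridge of
$10^{-8}\,\mathrm{tr}(S_p)/3$ and is counted in the output. A Shapiro–Wilk
screen reports the fraction of in-mask voxels whose three components all
pass at $\alpha = 0.05$; for Gaussian data with independent components that
fraction is $0.95^3 \approx 0.857$ by construction, which is what the test
asserts (a commonly quoted "$\ge 0.9$" is not attainable under the all-three
rule). Similarly, the power of the $T^2$ test for a 1-SD shift in one
component at $n = 20/20$ is the noncentral-$F$ value $\approx 0.70$, and the
test asserts agreement with that exact value rather than an optimistic
bound.

## The synthetic cohorts: what they emulate and what they do not

`make_template()` builds a smooth spherical phantom: a bright shell, a dark
central cavity, six tissue blobs of alternating contrast, a designated
structure at the effect site, and seeded low-frequency texture — enough
gradient information for intensity-driven registration throughout the
interior. `make_subject()` warps the template by a random smooth
inter-subject SVF (baseline anatomy), then applies a longitudinal SVF
composed of a shared aging field, a converter-only localized contraction
(volume loss, peak 2 voxels by default), and a subject-specific smooth noise
field, plus additive intensity noise. All randomness derives from one master
seed; ground-truth fields are returned and checked to be diffeomorphic.

Two fixture-design points deserve emphasis:

* **Aperture awareness.** Tangential motion of the nearly spherical rim is
  invisible to any similarity-driven registration (the aperture problem), so
  random ground-truth fields are supported in the textured interior, and the
  standard registration fixture adds a purely *radial* rim contraction.
  Without this, endpoint-error evaluations penalize information that no
  intensity-based method could recover, and the benchmark measures the
  phantom, not the algorithm.
* **Effect-region definition.** The seeded contraction has a Gaussian
  profile whose displacement extends to roughly three times its nominal
  radius, so the localization target (`effect_region_mask()`) is defined as
  the voxels where the true converter-only displacement exceeds 0.2 voxels,
  not a fixed-radius ball.

Chosen study conditions (fixed once): 15 converters and 15 stable subjects;
inter-subject anatomy 2 voxels peak; shared aging 0.5 voxels; subject-level
longitudinal variability 1 voxel (half the effect peak); intensity noise SD
0.02. Under these conditions the full pipeline at $32^3$ reaches pooled
10-fold accuracy 1.0 and localizes the effect with Dice ≈ 0.73 against the
thresholded truth; validation runs use $32^3$ grids (the generator default
is $48^3$) so the complete suite executes in minutes on one CPU.

What passing these tests does **not** show: robustness to MRI physics (bias
fields, Rician noise), to imperfect skull stripping or global alignment, to
anatomy outside the diffeomorphic model (lesions), or to effect sizes near
the detection floor. The phantom's separability is far higher than real
MCI-conversion cohorts, where reported accuracies are near 0.9, not 1.0.

## Transport validation and the norm-conservation check

Zero-change transport ($I_1 = I_0$) and identity transport ($T_0 = I_0$,
which must reproduce the direct longitudinal registration) are checked at
the default $\sigma = 1.5$. Approximate norm conservation — the transported
field's squared norm within 30% of the direct subject field's — is checked
at $\sigma = 1.0$: diffusion regularization attenuates every estimated
field, and that attenuation enters the ladder's output twice (steps 3 and 5)
but the direct field once, so at $\sigma = 1.5$ the ratio settles near 0.67
for structural reasons unrelated to the transport construction itself. At
$\sigma = 1$ the confound is small and the ratio is ≈ 0.82.

## Degenerate inputs and edge behaviour

Identical image pairs return an exactly zero SVF; constant images
short-circuit before optimization. All-zero gradients produce a zero demons
update with a message. $\sigma = 0$ runs to completion and reports the
minimum Jacobian determinant (possibly negative). Constant per-voxel samples
in the Shapiro screen count as passing (degenerate) and are tallied. Voxels
with truly degenerate pooled covariance contribute $T^2 = 0$. Ties in
template selection resolve to the lowest index; MDS clips negative
eigenvalues to zero with a warning.

## Known limitations

* Differential operators ignore anisotropic spacing; strongly anisotropic
  data should be resampled first.
* The demons force has no mask weighting; smoothing can bleed signal a few
  voxels outside the brain mask (visible as a thin halo in group maps).
* Geodesic length uses explicit Euler (16 steps by default); for fields
  with |v| near the grid scale, increase `integration_steps`.
* The BY correction addresses dependence but not spatial cluster inference;
  no random-field or permutation-based cluster correction is provided.
* Runtime scales linearly with voxel count times iterations; a $48^3$
  30-subject cohort takes roughly 3–4 times the $32^3$ figures quoted above.
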