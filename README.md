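# svfmorph

Longitudinal brain morphometry with stationary velocity fields.

Given pairs of co-registered 3D scans (baseline and follow-up) per subject,
**svfmorph** estimates each subject's anatomical change as a stationary
velocity field (SVF) by symmetric LogDemons diffeomorphic registration,
carries those fields into a common template space with Schild's Ladder
parallel transport, and analyses the normalized fields two ways:

* **subject classification** — converters (MCIc) vs. stable (MCIs) subjects
  from voxelwise features (SVF, Jacobian determinant, divergence, geodesic
  length, deformation), reduced by kernel PCA and classified with a linear
  SVM under stratified 10-fold cross-validation;
* **group localization** — a voxelwise two-sample Hotelling T² map on the
  SVF vectors with Benjamini–Yekutieli FDR correction.

It is aimed at researchers studying neurodegenerative progression (for
example conversion from mild cognitive impairment to Alzheimer's disease)
who want dense, whole-brain longitudinal change as the feature, rather than
a few regional volumes.

## The model in brief

Anatomical change is a diffeomorphism `φ = Exp(v)` parameterized by an SVF
`v`, estimated by minimizing the symmetric cost

```
‖F − M∘Exp(v)‖² + ‖M − F∘Exp(−v)‖² + Reg(v; σ)
```

with Gaussian regularization of `v` (σ = 1.5 voxels by default). `Exp` is
computed by scaling-and-squaring with a second-order flow start. Normalizing
a subject's longitudinal SVF into template space uses a single geometric
ladder: `v₁ = log(T₀→I₁)`, half-space image `P = T₀∘Exp(½v₁)`,
`v₂ = log(I₀→P)`, `T₁ = I₀∘Exp(2v₂)`, then `v_norm = log(T₀→T₁)`. The
template itself is chosen from the cohort baselines by classical MDS on
pairwise SVF-norm distances (nearest image to the embedding centroid).

Classification solves `min ‖w‖² + c Σ max(0, 1 − yᵢ(⟨w, fᵢ⟩ + b))` on
KPCA-reduced features with `c` chosen by nested grid search over
`{10⁻³, …, 10³}`. Group maps use
`T² = (n₁n₂/(n₁+n₂)) d̄ᵀ Sₚ⁻¹ d̄ ~ F(3, n₁+n₂−4)` per voxel.

See the methods vignette (`vignettes/svfmorph-methods.Rmd`) for the
numerical choices, parameter table and validation design.

## Worked example

Everything is testable without any data download: the package ships a
synthetic phantom generator with known ground truth. Register a known warp
and inspect the result:

```r
library(svfmorph)

fx  <- registration_fixture()             # 32^3 phantom + known 3-voxel warp
res <- logdemons_register(fx$fixed, fx$moving, registration_config(sigma = 1.5))
res
#> <registration_result mse 0.1064 -> 0.0008353, max |v| = 3.61 voxels, min JD = 0.396>

jd  <- jacobian_determinant(exp_svf(res$svf, 1))
msk <- unclass(fx$mask) > 0
range(unclass(jd)[msk])
#> volume-change range inside the brain mask: [0.41, 0.77]

epe <- sqrt(apply((unclass(exp_svf(res$svf, 1)) - unclass(fx$phi_true))^2, 1:3, sum))
mean(epe[msk])
#> mean endpoint error vs ground truth: 0.28 voxels
```

The mean squared difference drops to below 1% of its initial value, the
Jacobian determinant stays positive (a diffeomorphic result; values below 1
are the contraction the fixture seeded), and the recovered deformation is
within a third of a voxel of the ground truth on average.

A full cohort analysis from a manifest on disk:

```r
spec <- cohort_spec(n_converters = 15, n_stable = 15, shape = 32, seed = 7)
make_cohort(spec, dir = "cohort/")

cfg <- pipeline_config(manifest = "cohort/manifest.csv",
                       mask     = "cohort/mask.nii.gz",
                       template = "cohort/template.nii.gz",
                       output_dir = "run/")
res <- run_pipeline(cfg)
res$cv
#> <cv_report gaussian kernel: ACC=1.000 SEN=1.000 SPE=1.000 F1=1.000 AUC=1.000>
sum(unclass(res$sig_map))       # voxels significant at q <= 0.001
```

On this fully separable synthetic cohort the cross-validated metrics are
all 1.0 and the significant cluster overlaps the seeded atrophy region with
Dice ≈ 0.73. Per-subject normalized SVFs are cached under `run/vnorm/` and
reused on re-runs with an identical configuration.

A thin command-line wrapper over the same functions is installed at
`inst/cli/longidiff.R` with subcommands `simulate`, `register`, `transport`,
`select-template`, `groupmap` and `run`.

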