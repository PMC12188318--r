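# pcdtrack

Deformable liver motion tracking from a **single, arbitrarily angled cone-beam
x-ray projection**, for image-guided radiotherapy research. The package
implements a patient-specific conditional **point-cloud diffusion** framework:
a rigid alignment model estimates the liver's overall translation, and a
denoising diffusion model over per-node displacement vector fields (DVFs) of a
prior liver-surface point cloud iteratively refines the residual deformation,
re-conditioned at every denoising step on features pooled from the projection
through the exact cone-beam geometry. Estimated surface motion is propagated
to interior tumor points for localization.

Everything — anatomy, breathing motion, projections, noise — can be simulated
by the built-in phantom, so the full pipeline is exercisable and testable
without any patient data.

## The model in brief

With a variance schedule β₁…β_T (α_t = 1 − β_t, ᾱ_t = ∏ α_s), the forward
process over the normalized surface DVF X₀ is

    X_t = √ᾱ_t · X₀ + √(1 − ᾱ_t) · ε,   ε ~ N(0, I_{3N}),

and the reverse ancestral step uses the predicted noise
ε̂ = s_θ(X_t, t, C):

    X_{t−1} = ( X_t − β_t/√(1−ᾱ_t) · ε̂ ) / √α_t + √β_t · z.

The condition C is geometry-informed: every surface node is projected onto
multi-scale 2D feature maps of the x-ray projection and pools a feature
vector by bilinear interpolation (3840 values/node with the default
ResNet-50-width backbone). s_θ is a point-voxel network (voxelized 3D
convolution branch + per-point MLP branch, fused by addition). Training
minimizes

    L_total = L_noise + λ_sim·L_sim + λ_lap·L_lap + λ_eng·L_eng,
    λ_sim = 1, λ_lap = λ_eng = 0.01,

where L_sim is a node-wise MSE with the superior–inferior axis weighted 3×,
L_lap penalizes changes of Laplacian coordinates over an 8-nearest-neighbor
graph, and L_eng is the mean deformation energy of the predicted DVF.
Accuracy is reported as RMSE, 95th-percentile Hausdorff distance (HD95), and
tumor center-of-mass error (COME), all in mm.

## Worked example

```r
library(pcdtrack)

# a synthetic patient: liver, tumor, 10-phase breathing cycle
phantom <- make_phantom(seed = 1)
pm      <- build_phantom_motion(phantom)
print(phantom)
#> Liver phantom: 64x64x64 voxels @ 4.0 mm, 200 surface nodes, 40 tumor points

# one deformed + shifted target, imaged at gantry 40 deg
cfg  <- run_config(seed = 1)
case <- simulate_dataset(phantom, pm, cfg, n = 1, split = "test",
                         angles = 40, seed = 7)[[1]]
rmse_cloud(case$cloud_ref, case$cloud_tar)   # prior surface error (mm)
#> [1] 14.67

# train the two-stage model on simulated data and estimate the motion
trainset <- simulate_dataset(phantom, pm, cfg, cfg$n_train, "trainval",
                             seed = 11)
models   <- train_pipeline(trainset, cfg, seed = 23)     # a few minutes, 1 CPU
est <- sample_dvf(models$diffusion, models$rigid, case$cloud_ref,
                  case$views[[1]]$proj, case$views[[1]]$geom, seed = 1)
rmse_cloud(est$cloud_pred, case$cloud_tar)   # predicted surface error (mm)
#> [1] 12.11

# localize the tumor through the interior interpolant
come(phantom$tumor_points, case$tumor_tar)   # prior tumor error (mm)
#> [1] 18.11
tumor_pred <- localize_tumor(phantom, est$dvf, est$shift)
come(tumor_pred, case$tumor_tar)             # predicted tumor error (mm)
#> [1] 12.86
```

The printed numbers are from the desk-scale profile (64³ phantom, 128×96
detector, T = 100, tiny backbone, 48 training cases) and vary with seeds;
the point is the *prior → predicted* error reduction, whose size is limited
by the very small desk-scale training budget — this test phase carries
large deformation plus a rigid setup shift, and a few minutes of CPU
training recovers only part of it. `run_benchmark()` wraps the same flow
over a full test set at nine gantry angles and returns a `metric_report`
with prior and predicted RMSE/HD95/COME; `run_noise_sweep()` re-evaluates
at photon fluences 10³–10⁶ (per reference detector pixel), and
`run_ablation()` compares the full model with the no-rigid (NR) and
no-geometry-pooling (NG) variants.

A thin command-line wrapper is installed at `inst/cli/pcdtrack.R`
(`make-phantom`, `simulate`, `benchmark`, `evaluate`), reading and writing
plain-text PLY/TSV/JSON.

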