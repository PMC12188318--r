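---
title: "Deformable liver motion tracking from a single x-ray projection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable liver motion tracking from a single x-ray projection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pcdtrack)
```

## The problem

During liver radiotherapy the target moves with respiration by up to a few
centimetres, predominantly along the superior–inferior (SI) axis. On-board
imaging during treatment is usually limited to single 2D cone-beam x-ray
projections, which are fast to acquire but lack depth information, and the
liver is a low-contrast organ on x-rays. `pcdtrack` implements a
patient-specific framework that estimates the *deformable 3D motion of the
liver surface* — a per-node displacement vector field (DVF) over a prior
surface point cloud — from one arbitrarily angled projection, and propagates
that surface motion to interior tumor points for localization.

The framework has two trained components:

1. a **rigid alignment model** that predicts the liver's overall translation
   (setup error plus bulk motion) from features pooled at the reference
   cloud, and
2. a **conditional point-cloud diffusion model** that refines the residual
   deformable motion by iterative denoising, re-conditioning on the
   projection at every step.

Everything runs on synthetic data produced by the package's own phantom, so
the entire pipeline is testable without patient data.

## Diffusion over surface DVFs

The diffusion state is the per-node DVF in normalized units. With a variance
schedule $\beta_t$, $\alpha_t = 1-\beta_t$,
$\bar\alpha_t = \prod_{s\le t}\alpha_s$, the forward process is the standard
closed form
$$X_t = \sqrt{\bar\alpha_t}\,X_0 + \sqrt{1-\bar\alpha_t}\,\epsilon,\qquad
\epsilon \sim \mathcal N(0, I_{3N}),$$
and the reverse (ancestral) step uses the predicted noise
$\hat\epsilon = s_\theta(X_t, t, C)$:
$$X_{t-1} = \frac{1}{\sqrt{\alpha_t}}\Big(X_t -
\frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\hat\epsilon\Big) + \sqrt{\beta_t}\,z,$$
with $z = 0$ at $t = 1$. We use the simplest DDPM variant with reverse
variance $\sigma_t^2 = \beta_t$; the schedule is linear ($10^{-4}$ to
$2\times 10^{-2}$), with $T = 1000$ at paper scale and $T = 100$ in the
desk-scale profile.

Diffusion models produce near zero-centred outputs, so the rigid translation
is handled separately: the clean state is the *deformable residual*
$X_0 = (X_\mathrm{tar} - X_\mathrm{ref} - s)/\sigma$ where $s$ is the rigid
shift predicted by the frozen alignment model and $\sigma$ is a fixed
normalization scale (default 10 mm — roughly the magnitude of peak
respiratory displacement, so normalized states are $O(1)$). The complete DVF
returned by `sample_dvf()` is $\sigma X_0 + s$.

### Conditioning: geometry-informed feature pooling

A stack of multi-scale 2D feature maps is extracted from the projection by a
jointly trained convolutional backbone. Each surface node is projected
through the exact cone-beam geometry onto the detector; its continuous pixel
coordinate, divided by each map's downscale factor, addresses every map by
bilinear interpolation, and the sampled values are concatenated into one
feature vector per node. At paper scale the backbone mirrors the four stage
outputs of a 50-layer residual network (256/512/1024/2048 channels,
downscales 4/8/16/32 — 3840 values per node). The desk-scale backbone is a
small strided-convolution pyramid (8/16/32 channels) with the standardized
projection itself prepended as a downscale-1 map, which gives the pooling
layer direct access to the raw line integrals; the diagnostic value of that
raw channel is that translation and magnification cues survive without
having to be re-learned from scratch at small sample sizes.

During sampling, the intermediate cloud
$X_\mathrm{ref} + \sigma X_t + s$ is re-pooled at *every* denoising step, so
the condition tracks the current cloud estimate (the angle-agnostic property:
nothing in the model depends on the gantry angle except through the pooling
geometry).

### The point-voxel network

The noise predictor and the rigid regressor share one architecture: a
point-voxel network. Input rows are `[x_t | condition]` (width $3 + F$). The
voxel branch translates the first three columns to their centroid, scales
into the unit sphere, averages features over a regular grid (default
$16^3$, desk scale $8^3$), applies two 3×3×3 convolutions, and maps back to
the points by trilinear devoxelization; the point branch is a shared
two-layer per-node MLP; the branches are fused by addition. Timesteps enter
through a sinusoidal embedding passed through a dense layer and added to the
hidden features.

Two output paths supplement the fused head (which is zero-initialized):

* a zero-initialized **linear skip** from the raw input row, so that linear
  read-outs of the condition (and of $x_t$, whose optimal noise prediction
  is strongly linear) are reachable without traversing the deep path;
* a **global context** path — the node-averaged hidden features pass through
  a small MLP whose output is added to every node — providing cross-node
  integration at full feature resolution (cloud-level cues such as
  magnification live there). Outputs remain per-node, so the rigid model's
  mean-over-nodes contract is unchanged.

All layers are plain dense/convolutional maps implemented on BLAS with
hand-derived gradients (no deep-learning framework is involved), optimized
by Adam with gradient accumulation over 4 samples, global gradient-norm
clipping at 5, and linear learning-rate decay to 10% of the initial rate
(defaults $10^{-3}$ to $2\times10^{-3}$). Clipping and decay are standard
stabilizers; without them long runs of the composite objective diverge
because the reconstruction losses scale the noise-prediction gradient by
$\sqrt{1-\bar\alpha_t}/\sqrt{\bar\alpha_t}$, which is an order of magnitude
at $t \approx T$.

### Losses

Training minimizes
$$L_\mathrm{total} = L_\mathrm{noise} + \lambda_\mathrm{sim} L_\mathrm{sim}
+ \lambda_\mathrm{lap} L_\mathrm{lap} + \lambda_\mathrm{eng} L_\mathrm{eng},
\qquad \lambda_\mathrm{sim} = 1,\ \lambda_\mathrm{lap} = \lambda_\mathrm{eng}
= 0.01.$$

* $L_\mathrm{noise}$: mean squared error between true and predicted noise.
* $L_\mathrm{sim}$: node-wise MSE between the reconstructed and target
  clouds with the *SI term scaled by 3* (liver motion is SI-dominant).
* $L_\mathrm{lap}$: mean squared change of Laplacian coordinates
  $\delta_p = p - \frac{1}{|\mathcal N(p)|}\sum_{q\in\mathcal N(p)} q$ over
  an 8-nearest-neighbor graph built once on the reference cloud (fixed node
  correspondence); exactly invariant to rigid translations.
* $L_\mathrm{eng}$: mean dot product between each node's DVF and its graph
  Laplacian — zero for spatially uniform fields, and possibly *negative* for
  asymmetric k-NN graphs (the directed graph Laplacian need not be positive
  semi-definite); we assert and document this rather than symmetrize it.

The similarity and regularization terms are evaluated on the cloud implied
by the reconstructed clean state
$\hat X_0 = (X_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/\sqrt{\bar\alpha_t}$,
compared against the target (for $L_\mathrm{sim}$) and the reference (for
$L_\mathrm{lap}$, $L_\mathrm{eng}$). The source formulation leaves open at
which diffusion state the regularizers act (consecutive states vs the
reconstruction); we chose the reconstruction because it makes every step's
regularization refer to the same physical object and keeps the gradient
path short. This is a documented choice, not an assertion about the original
intent.

## The digital phantom and motion model

The phantom is a superellipsoidal liver (default semi-axes 60/45/70 mm,
exponent 2.5) with configurable contrast against a soft-tissue body,
smoothed random texture, a spherical tumor strictly inside the surface, and
a Fibonacci-lattice surface cloud lying exactly on the superellipsoid (hence
within one voxel of the binary mask boundary). Breathing is an analytic
three-component family — an SI-dominant bulk displacement (9 mm), an AP tilt
varying along SI with phase lag (3 mm), and a localized radial bulge
(2 mm) — evaluated over a 10-phase cycle with phase 1 (0%) as the zero
reference. The amplitudes reproduce the SI ≫ AP ≫ LR ordering reported for
liver motion.

The PCA motion model (mean field + top-3 principal components with per-phase
scores) is fitted *jointly* over the voxel grid, the surface nodes and the
tumor points stacked into one representation, so a synthesized weight vector
yields exactly consistent volumetric, surface and tumor fields — the warped
image, the surface targets and the tumor ground truth cannot drift apart.
(An alternative would be to extend surface DVFs into the volume through the
interior interpolant at rendering time; the joint PCA is cheaper and exactly
self-consistent, which is why we adopted it.)

The augmentation plan reproduces the study protocol exactly: per training
phase, 4/6/4/2 uniform scaling factors for coefficients $w_0\ldots w_3$ over
$[0.95,1.05]$, $[-1.5,3.0]$, $[-1.5,3.0]$, $[-1.5,1.5]$, expanded as a
Cartesian product (192 deformations/phase over 6 phases), randomly split 2:1
into train/validation (the split mechanism is unstated in the source; we use
a seeded random assignment with exact counts), each deformation yielding one
untranslated plus three translated volumes (translations uniform in
$[-6,6]$ mm per axis) — 768/384 deformations and 3072/1536 volumes. Testing
uses 3 phases × 15 coefficient combinations ($w_0 = 1$, $w_1, w_2 \in
[0,4]$, $w_3 \in [0,2]$ — we sample $w_2$ as well, resolving the protocol's
ambiguous wording), each yielding three translated volumes only
(translations in $[0,10]$ mm), i.e. 45 test cases and 135 volumes; at nine
equally spaced gantry angles that is 1215 test projections. The
per-coefficient samples are redrawn per phase.

## Projector

Gantry rotation is about the SI axis; gantry 0° puts the source on the +AP
axis (any fixed convention works — projection and pooling share this one).
SAD/SDD default to 1000/1500 mm (typical on-board imager values; the source
does not state them). Detector pixels are continuous coordinates with the
origin at the corner pixel centre; the isocenter projects to the detector
centre. DRRs are line integrals by midpoint-rule ray marching at steps of
half a voxel with trilinear sampling; rays are clipped to the volume's
bounding box.

Detector noise follows the study's model: Poisson counts with mean
$I_0 e^{-g}$ plus zero-mean Gaussian electronic noise (s.d. 10 photons),
clamped at one count, mapped back to the line-integral domain. Noise is
applied in the count domain because the feature extractor consumes
log-domain projections. The printed fluence levels ($10^3$–$10^6$, training
at $10^5$) are *per 0.776 mm detector pixel*; when the desk-scale profile
uses coarser pixels, the per-pixel mean is scaled by pixel area
(`photons * (pitch/0.776)^2`) so the flux per unit detector area — the
physically meaningful quantity — matches the study's conditions at every
detector resolution. Without this scaling, a 3 mm desk-scale pixel would
simulate a beam ~15× weaker than intended, and the depth (magnification) cue
that the rigid model needs — sub-pixel edge displacements of order 0.2 px
for a 6 mm AP shift — drops below the quantum noise floor.

## The rigid alignment model at desk scale

The rigid model regresses the liver's overall translation from features
pooled at the reference cloud; the per-node 3-vector outputs are averaged
into one shift. Three design choices make this learnable at desk-scale
sample sizes:

* **Angle canonicalization.** The gantry angle is known exactly at
  inference, so the regression is posed in the source frame: node
  coordinates are rotated by minus the gantry angle before entering the
  network, and the predicted shift is rotated back. In-plane translation and
  depth (magnification) cues then relate to the inputs identically at every
  angle.
* **Coordinate-modulated inputs.** Each node row carries the pooled features
  and their products with the normalized node coordinates. After averaging
  over nodes, a linear read-out of these products equals a feature read-out
  whose weights vary linearly across the surface — exactly the form of the
  radial magnification pattern that encodes depth. Without this, the
  network must synthesize position-dependent read-outs through its deep
  path, which plain stochastic training does not find within desk budgets.
* **Closed-form warm start.** The linear skip is initialized by a ridge
  regression of the (source-frame) shifts on the node-averaged augmented
  inputs — the same MSE objective restricted to the skip's subspace, solved
  exactly — and Adam then refines all parameters jointly. The design matrix
  is strongly ill-conditioned, so first-order steps alone converge far too
  slowly.

Depth (the axis along the central ray) remains the accuracy bottleneck: a
6 mm shift toward the source moves the liver silhouette by only ~0.2 detector
pixels at the desk-scale geometry, and that cue competes with quantum noise.
Noiseless-projection experiments confirm the depth signal is linearly
decodable to well below 0.1 mm, i.e. the limitation is photon statistics at
this detector scale, not the model: in-plane components recover to a few
tenths of a millimetre, while the depth component saturates near 1.5–2.5 mm
at the study fluence. The shift-recovery benchmark (`rigid_benchmark()`)
therefore reports mean errors above 1 mm even though predicted shifts beat
the zero-shift prior on essentially every held-out case. At the printed
full detector resolution (0.776 mm pixels) the cue is sampled 16× more
densely, which is why this limitation is specific to the scaled-down
profile.

## Interior propagation and tumor localization

The predicted surface DVF is decomposed into a spatially uniform DC part
(per-axis mean; rigid-like) and the residual AC part. Only the AC part is
interpolated into the interior — by a polyharmonic spline ($\varphi(r) = r$,
the biharmonic kernel in 3D) with affine terms fitted per axis at the
surface nodes, ridge-regularized at $10^{-6}$ to tolerate noisy inputs — and
the DC part is added back. The interpolant reproduces affine fields exactly
and the surface values up to the regularization tolerance. It is a
deterministic, synthetic stand-in exposing the same interface (surface DVF
in, AC-only internal input, interior field out) as a learned biomechanical
model, so such a backend can be swapped in; finite-element mechanics is out
of scope. Consequently tumor-localization error through this interpolant
measures the interpolant, not a biomechanical model, and absolute clinical
COME values are not comparable.

## Metrics

* `rmse_cloud`: corresponding-node RMSE (a correspondence metric).
* `hd95`: symmetric 95th-percentile directed nearest-neighbor distance; the
  percentile uses linear interpolation between order statistics (a
  nearest-rank variant is provided for sensitivity checks; the convention is
  unstated in the source).
* `come`: distance between unweighted centroids of the tumor point sets
  (no volume weighting, which the source does not specify).

All three are invariant under joint rigid motion of both inputs; `hd95`
never exceeds the exact Hausdorff distance.

## Desk-scale profiles and what the tests show

The default `run_config()` profile — 64³ voxels at 4 mm, 200 surface nodes,
128×96 detector at 3 mm, T = 100, a 3-stage backbone with the raw input
map, hidden width 32, voxel grid 8³ — is sized so the full two-stage
training, sampling and evaluation complete on one CPU core in minutes. The
acceptance benchmarks use these sizes with training sets of ~100 cases; the
test suite uses smaller instances still. The paper-scale profile (512×384
detector at 0.776 mm, T = 1000, the 3840-channel backbone, thousands of
augmented volumes, 200k training steps) is expressible through the same
configuration object but is not exercised by the tests.

Synthetic data mimic the *statistical structure* of the clinical problem
(SI-dominant three-component motion, setup shifts, cone-beam geometry,
quantum noise, low liver contrast) but not its anatomy: one smooth organ,
no ribs or gas pockets, no scatter, monochromatic attenuation, identical
texture across cases. Passing the recovery benchmarks therefore demonstrates
that the machinery — simulation, conditioning, training, sampling,
propagation, metrics — is implemented correctly and can extract the
geometric signal at desk scale; it does not certify clinical accuracy, and
the study's patient-data error tables are out of reach by construction.

## Numerical choices and edge cases

* k-NN distance ties break by ascending node index — graphs are
  deterministic even with duplicated coordinates.
* Points at or behind the x-ray source plane are flagged invalid by
  `project_points`, never an exception; out-of-view nodes pool zeros, with
  a warning if more than half the cloud leaves the detector.
* The ReLU at zero-initialized biases sits exactly at its kink for empty
  voxels; the backward pass uses the subgradient 0 there (finite-difference
  checks intentionally exclude that point).
* `hd95` recomputes argmin distances exactly instead of trusting the
  quadratic expansion, so identical clouds give exactly 0.
* Degenerate (coplanar) surface nodes make the spline system singular and
  raise an error.
* Volume warping is pull-back with the forward field (`x - D(x)`); for the
  simulated displacement magnitudes the forward/inverse discrepancy is
  second-order and identical for training and evaluation data, so it does
  not bias comparisons.
* All stochastic stages take explicit seeds; trainers restore the caller's
  RNG state.

## Known limitations

* The rigid model handles translations only (as in the source framework).
* No scatter, beam hardening, or detector blur in the projector.
* The interior propagation is an interpolant, not mechanics.
* Depth (the axis along the central ray) is fundamentally the hardest
  component to recover from a single projection; its accuracy is
  noise-limited through the magnification cue.
* Desk-scale training budgets are small; the diffusion model's sample
  quality at paper scale is not established by this package's tests.
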