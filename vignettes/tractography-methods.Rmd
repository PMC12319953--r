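---
title: "Model and methods: learned streamline propagation with von Mises-Fisher sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: learned streamline propagation with von Mises-Fisher sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Diffusion MRI of the fetal brain is acquired under severe constraints: short
scans, low b-values, thick slices, and fetal motion. After motion correction
the per-voxel diffusion tensor fit is noisy, and fractional anisotropy (FA)
in fetal white matter is low — roughly 0.05 to 0.25 rather than the 0.3-0.8
typical of adult tracts. Classical streamline tractography, which turns the
local fiber orientation into the next propagation step, fails often in this
regime because the local orientation estimate is simply not reliable enough.

`vmftract` implements a machine-learning alternative: the next propagation
direction is *predicted* from five complementary sources of information
rather than read off the local peak. The five sources are

1. a multi-scale neural encoding of the whole diffusion-ODF volume
   (a transformer-plus-convolution encoder/decoder producing a three-scale
   feature pyramid), interpolated at the current point and at a look-ahead
   point, plus the raw features on the 3x3x3 voxel neighborhood;
2. convolutional encodings of the tissue segmentation map;
3. convolutional encodings of a two-fixel direction prior volume;
4. the streamline propagation history at lags 1, 3, 5, 7, 9 and 11 steps;
5. a global position encoding — the normalized distances to the centroids
   of five fixed, non-coplanar anatomical regions.

A fully connected head maps the concatenated features to spherical
coordinates $(\theta, \phi)$ of the next step direction.

## Directional statistics

Step directions are modeled with the von Mises-Fisher (vMF) distribution on
the 2-sphere,
$$p(u;\mu,\kappa) = C(\kappa)\, e^{\kappa \mu^\top u}, \qquad
  C(\kappa) = \frac{\kappa}{4\pi\sinh\kappa},$$
with mean direction $\mu$ and concentration $\kappa \ge 0$ ($\kappa = 0$ is
the uniform distribution on the sphere). Rather than learning $\kappa$, the
package ties it to the local tensor anisotropy:
$$\kappa = \alpha\,\mathrm{FA}^2, \qquad \alpha = 1600 \text{ by default},$$
so the fetal FA range $[0.05, 0.25]$ maps to $\kappa \in [4, 100]$. Two
working points are useful to keep in mind: FA $0.20 \to \kappa = 64$, a 90%
cone of about $12^\circ$; FA $0.10 \to \kappa = 16$, about $24^\circ$. The
"90% cone" here is the Gaussian tangent-plane approximation
$1.645/\sqrt\kappa$ radians, which is the conventional way these cone widths
are quoted; the exact vMF angular quantile is narrower, and
`angular_spread90()` documents that it returns the approximation.

Sampling uses the closed-form inverse CDF of $t=\cos\angle(u,\mu)$:
with $\xi \sim U(0,1)$,
$t = 1 + \log\!\big(\xi(1-e^{-2\kappa}) + e^{-2\kappa}\big)/\kappa$,
a uniform azimuth in the tangent plane, and a rotation of the $+z$ frame
onto $\mu$. This is exact and rejection-free, remains stable for large
$\kappa$ (log1p form), and degrades gracefully to exact uniform sampling at
$\kappa = 0$, which matters because phantom background voxels have FA $= 0$.

## Training

Each training sample is one point on one reference streamline; its target is
the unit vector to the next point. Targets are *augmented* with vMF noise,
$u_{aug} \sim p_{vMF}(u_{target}, \alpha \mathrm{FA}^2)$, redrawn every
epoch, so that low-FA points contribute noisier targets; the default loss is
the cosine similarity $-\langle u_{pred}, u_{aug}\rangle$. The full vMF
negative log-likelihood $-\kappa\langle u, \hat u\rangle - \log C(\kappa)$
is implemented as an alternative (`train_config(loss = "vmf_nll")`); with
$\kappa$ fixed from FA it weights confident samples more strongly, which the
test suite verifies as a monotone gradient-magnitude property.

The optimizer is SGD with momentum 0.9. Desk-scale specifics, each chosen
once while designing the training loop:

* **Input standardization.** The assembled feature vector mixes SH
  coefficients (magnitude ~0.1), convolution outputs, history components
  (±1) and position encodings (~0.2); their scales differ by orders of
  magnitude and raw SGD does not break the antipodal target symmetry before
  it stalls. Per-feature location/scale are estimated once from the training
  set (with the initial encoder weights), stored in the model, and applied
  identically at training and inference. Near-constant features are left
  unscaled rather than amplified.
* **Warm-up, joint phase, polish.** Training all modules jointly from
  random initialization is unstable at small scale: the encoder receives raw
  gradients orders of magnitude larger than the head's. `train_model()`
  therefore first trains the head against the frozen initial encoders
  (`warmup_epochs`), then opens the full computational graph for
  `joint_epochs` — gradients flow through the feature gathers, decoder,
  transformer and patch embedding to every parameter — with per-module
  gradient-norm clipping (`clip = 5`), a reduced encoder rate
  (`enc_lr_scale = 0.02`) and a reduced head rate (`joint_lr_scale = 0.1`),
  and finally re-freezes the encoders so the head re-converges to the
  updated feature distribution. Without the polish phase the encoder drift
  of the joint epochs leaves the head miscalibrated by more than the loss
  (which is dominated by augmentation noise) reveals: direction precision
  on held-out geometry degrades markedly, which is how this schedule was
  settled. The default learning rate (0.05) is larger than
  the $10^{-3}$ a full-scale GPU run would use; the scaled-down model,
  standardized inputs and full-batch regime support it, and the defaults are
  exposed in `train_config()`.
* **Plateau stopping.** Training stops when the epoch loss has not improved
  on its best value by more than `tol = 1e-3` for `patience = 10` epochs, or
  at `max_epochs`.
* **History at the first point.** A fresh streamline has no previous step;
  its history buffer is seeded with the launch direction (at training time,
  the first step of the reference streamline), mirroring how seeds carry an
  initial direction at test time. Deeper missing lags always repeat the
  oldest available direction.

## Tracking

Seeding follows the gray-white interface: every cortical gray-matter voxel
with a white-matter 6-neighbor launches five streamlines toward each such
neighbor, with uniform position jitter of ±0.6 mm per axis and ±30° jitter
on the polar and azimuth angles of the launch direction. The launch step
itself follows the (jittered) seed direction; from the second step onward
the model predicts the mean direction $\mu$ and the tracker draws the actual
step from $vMF(\mu, \alpha \mathrm{FA}^2)$, moving 0.6 mm per step (half a
voxel). Because no single $\alpha$ suits every tract curvature, tracking
runs at $\alpha \in \{1600, 3200, 6400\}$ and merges the accepted
streamlines.

Anatomical constraints (nearest-voxel label lookup): a next point in white
matter continues; cortical or subcortical gray matter terminates and
accepts; CSF, background, or leaving the grid rejects; streamlines longer
than 130 mm are discarded. Two readings of the rules were settled as
follows. First, "neighboring" voxels are 6-connected (face-sharing), the
natural interpretation of a tissue boundary. Second, a streamline whose
launch step lands directly back in gray matter never traversed white matter
and is rejected rather than accepted — anatomically constrained tractography
means connecting gray-matter regions *through* white matter, and accepting
such two-point streamlines would flood density maps with boundary voxels.
Subcortical gray matter is accepted as an endpoint but (like the reference
approach) not used for seeding.

Determinism: one master seed drives everything through named substreams.
Seed generation consumes one stream; every (streamline, $\alpha$) pair gets
its own pre-generated uniform sequence, so results are independent of
iteration order and exactly reproducible.

## The ODF representation

Diffusion tensors are converted to the Gaussian-diffusion orientation
distribution $ODF(u) \propto (u^\top D^{-1} u)^{-3/2}$ (normalized to unit
integral; the closed-form normalizer is $4\pi\sqrt{\det D}$), evaluated on
an antipodally symmetric Fibonacci point set (724 points) and least-squares
fitted with a real, even-degree spherical-harmonic basis of order 8 — 45
coefficients per voxel. The basis is orthonormal, ordered by degree
$l = 0, 2, \dots, 8$ and order $m = -l..l$ with $\sin$ terms at negative
$m$; any consistent convention works since the encoder consumes the
representation end to end, and the tests pin this one. Eigenvalues are
floored at $10^{-6}\,\mathrm{mm^2/s}$ before inversion so background voxels
become tiny isotropic tensors instead of singular ones.

Interpolation conventions: voxel centers sit at integer 0-based continuous
voxel coordinates; world positions come from the NIfTI affine; streamlines
are stored in world mm. Pyramid level $s$ is sampled at $p/2^{s-1}$ in its
own voxel coordinates, with border replication on the half-voxel rim that
coarse grids do not cover. The 27-voxel raw-feature block uses the
full-resolution (F1) level only: extending it to all scales would several
times exceed a plausible input budget for the head, and F1 carries the
finest local structure. Edge voxels clamp the window.

## The synthetic phantom

`make_phantom()` builds every input with known ground truth: tubes around
straight, arc or polyline centerlines filled with prolate tensors whose
principal axis follows the local tangent and whose eigenvalues are solved in
closed form to hit a linear FA profile (default 0.25 at the axis to 0.05 at
the edge — exactly the $\kappa \in [4,100]$ regime) at fixed mean
diffusivity $10^{-3}\,\mathrm{mm^2/s}$; overlapping tubes average tensors
and record both tangents as the first two fixels; gray-matter caps
(thickness 2.4 mm, about cortical thickness) cover the flat end faces of
each tube — beyond the centerline ends, not sleeving the tube sides, where
real cortex would not sit — so seeds launch roughly axially; a CSF rim
surrounds the brain; five labeled balls at non-coplanar positions stand in
for the cortical parcellation keypoints. Ground-truth streamlines are
centerline-parallel curves at random in-tube offsets, resampled at 0.6 mm
and emitted in both orientations, since fibers carry no intrinsic
orientation and the tracker must handle seeds from either end.

What the phantom does *not* emulate: realistic fetal anatomy and cortical
folding, gestational-age dependence, dMRI noise with a realistic spatial
structure, partial-volume mixtures beyond two crossing tubes, registration
error in the fixel prior, and segmentation error. Passing the phantom suite
therefore shows that the machinery — representation, training, sampling,
anatomical rules, metrics — is correct and recovers known geometry from
consistent inputs; it does not certify accuracy on clinical fetal data.

## Evaluation

Tract masks are built as in tract-density imaging: each streamline is
resampled at half-voxel spacing and contributes at most 1 to every voxel it
visits; voxels strictly below the 5th percentile of the *nonzero* density
values are removed (including zeros would make the percentile trivially 0).
Dice, precision and recall compare the reconstruction with the ground-truth
tube. On a seeded 48^3 single-arc phantom, the full pipeline — phantom,
training (small encoder configuration: 8^3 patches, embedding 32, one
transformer block of two units, pyramid widths 8/16/32), tracking at the
three $\alpha$ levels — recovers the bundle with Dice above 0.7; the
dedicated test in `tests/testthat/test-acceptance.R` computes exactly this,
and `scripts/acceptance.R` recomputes the analytic working points.

Problem sizes used by the test suite were chosen to exercise every code
path at desk scale: 33^3 grids for unit tests, the 48^3 arc for the
end-to-end recovery, $10^5$ draws for sampler moment checks, and quadrature
to $10^{-6}$ for the normalizer.

## Known limitations

* The trained models here are phantom-scale; the full-scale configuration
  (128^3 grids, widths 64/128/256, batch 16,000) runs through the same code
  path but is far beyond a single-CPU session.
* The decoder topology between the stated pyramid shape contract and the
  transformer output is one reasonable choice (nearest-neighbor upsampling
  + convolution, an input-convolution skip into F1); the shape contract,
  not the topology, is what downstream code relies on.
* $\kappa$ is heuristic ($\alpha\,\mathrm{FA}^2$), not learned; the loss
  supports learning it in principle but that is deliberately out of scope.
* The NIfTI-1 header stores the affine in float32, so affines round-trip to
  about $10^{-7}$ relative accuracy, not bit-exactly.
* Polyline bundles measure distance to a densely sampled centerline
  (rounded tube ends); straight and arc bundles use exact geometry with
  flat ends.
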