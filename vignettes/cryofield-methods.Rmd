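---
title: "Reconstruction by differentiable rendering: the models behind cryofield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction by differentiable rendering: the models behind cryofield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cryofield reconstructs a 3D cryo-EM density map from a stack of 2D particle
images whose pose (orientation and in-plane shift) and contrast transfer
function (CTF) are known, by fitting a trainable scalar field end-to-end
through a differentiable model of image formation. This vignette explains
the model, its assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## The forward model

Under the weak-phase and projection approximations, an observed particle
image is

    y = PSF * P_z[ f(R^-1 x - t) ] + noise,

where `f` is the specimen's scalar density in a fixed canonical frame,
`R` is the particle's rotation, `t = (t_x, t_y, 0)` its in-plane shift,
`P_z` orthogonal projection along the viewing axis, `PSF *` convolution
with the microscope's point-spread function, and the noise is per-pixel
i.i.d. Gaussian with variance `sigma^2`.

cryofield discretizes this by *rotating the query grid, not the volume*:
a fixed microscope-frame lattice (one point per image pixel in the imaging
plane, `n_z` depth samples covering the same physical extent along the
viewing axis) is posed into the canonical frame, the field is queried at
those points, and the samples are summed to pixels through a sparse binary
matrix `M` whose (pixel, grid-point) pattern is pose-independent — so `M`
is built once per grid (or per grid/mask pair). The CTF is applied as an
element-wise multiplication in Fourier space using the RELION/CTFFIND
parametric form

    CTF(g) = -( sqrt(1 - A^2) sin chi + A cos chi ),
    chi    = pi lambda g^2 dF(theta) - (pi/2) Cs lambda^3 g^4 + phase_shift,

with astigmatic defocus `dF(theta)` from `defocus_u`, `defocus_v` and the
astigmatism angle. Every step — query, projection, CTF — is linear or
smooth, so the pixel loss differentiates back to the field parameters.
The package implements this adjoint chain analytically (the CTF operator
is self-adjoint; the projection's adjoint is `M^T`; the encoders have
hand-derived backward kernels), and the test suite checks the whole chain
against finite differences.

Coordinates are physical Angstroms with the box center at the origin;
grid points sit at pixel centers, `(i - n/2 + 0.5) * pixel_size`. The
depth spacing is `extent / n_z`, which covers the full box for any `n_z`
and degenerates to the single plane `z = 0` at `n_z = 1`. Field
parametrizations consume coordinates through one affine map onto the unit
cube. One consequence of the even-box FFT layout is that the astigmatic
CTF is not exactly conjugate-symmetric on the Nyquist row/column; the
package keeps the real part after filtering, which is the standard
treatment.

## Scalar-field parametrizations

Three interchangeable parametrizations implement `f`:

* **Hash grid** (the flagship): `L = 8` geometrically scaled resolution
  levels from `base_resolution = 16` up to a finest resolution matched to
  the Nyquist frequency of the observations (`n/2` for an `n`-pixel box).
  Each level stores a table of `2^log2_hashmap_size` feature rows of
  length `F = 2`; a queried point trilinearly interpolates the features of
  its 8 surrounding corners per level (dense indexing when the level's
  lattice fits the table, otherwise the standard spatial hash — XOR of the
  corner indices multiplied by the fixed large primes 2654435761 and
  805459861, modulo the table size; hash collisions are accepted and
  resolved by gradient averaging). The concatenated `L*F` features feed a
  2-hidden-layer ReLU MLP (64 or 128 neurons) with a linear scalar
  output. A single decoder is used. Tables initialize uniformly in
  ±1e-4. Out-of-box queries clamp to the boundary. At `2^10` tables with
  a 128-neuron decoder the closed-form parameter count is ≈35k, growing
  to ≈11M at `2^22` — the operating range for realistic box sizes.
* **Voxel field**: a trainable `n^3` array queried by trilinear
  interpolation, zero outside the box. Many more parameters for the same
  resolution; included as the real-space baseline.
* **Frequency field**: 8 octaves of sin/cos positional encodings per axis
  into the same MLP shape — the classic coordinate-network baseline, sized
  (128 neurons) to land near the 2×10^5-parameter regime.

## Jittering

Before querying, every grid coordinate is perturbed by an independent
Uniform(-J/2, J/2) draw (re-drawn at every forward pass, so each gradient
step sees fresh noise). In expectation this convolves the learned field
with a width-`J` top-hat per axis — multiplication by a sinc in Fourier
space — and acts as a real-space low-pass regularizer against noise
overfitting without ever filtering the data. `J` is in Angstrom;
`J = 0` disables it; values around 1–2.5 Å trade resolution against noise
robustness on the synthetic phantoms. The sinc equivalence is verified
directly in the acceptance suite by comparing the average of thousands of
jittered renders with the analytic top-hat convolution and its spectrum.

## Losses

All three objectives derive from the Gaussian white-noise model:

* `loss_mse`: `(1/(2 sigma^2)) sum (y - yhat)^2` — the plain negative
  log-likelihood with known noise level.
* `loss_cc`: both images are standardized per image (population standard
  deviation), then compared in the MSE sense; algebraically
  `(n^2/sigma^2)(1 - r)` for their Pearson correlation `r`. It is exactly
  invariant to global multiplicative (positive) and additive rescaling of
  either image, and `sigma` only scales it. This is the default
  experimental loss, with `sigma = 3`.
* `loss_bioem`: the likelihood marginalized analytically over a global
  scale and offset of the prediction, with the noise level removed by a
  saddle-point step. A flat prior over the scale makes this objective
  minimizable by driving the prediction to zero — a real numerical
  failure mode — so the package derives it under a Gaussian prior
  centered at scale 1 / offset 0 with a broad standard deviation
  (default 10). The loss then depends on the images only through
  `n^2, sum(y), sum(yhat), sum(y^2), sum(yhat^2), sum(y yhat)`. Two
  numerical details: a floor of `1e-9 * max(sum(y^2), 1)` inside the log
  keeps the loss finite when prediction and observation agree exactly,
  and its gradient is computed by complex-step differentiation of the
  three prediction-dependent sufficient statistics, which is exact to
  machine precision.

Batch reduction is the sum of per-particle losses.

## Heterogeneity by bending space

Conformational heterogeneity is modelled in the Eulerian, reverse-mapping
sense: instead of displacing mass, the query coordinates are bent into a
single canonical density. A shared encoder maps each image to a coarse
canonical vector field of shape `(n_F, n_F, n_F, 3)` (default
`n_F = 8`), which is trilinearly interpolated *at the posed, jittered
query points* and added to them before the field query. Because the
canonical field lives in the fixed frame and is only ever sampled at
pose-specific points, the per-image deformation transforms consistently
with pose (SE(3)-equivariant); the coarseness of the lattice is itself
the smoothness regularizer. A zero field reproduces the homogeneous
pipeline bit-for-bit.

The encoder is a fixed average-pooling front end (default: the full
image, capped at 24×24; the pooled image is standardized per image,
mirroring the loss's invariance to global image scale) followed by a
2-hidden-layer tanh trunk and a zero-initialized linear head, so
training starts exactly at the homogeneous model. A pooled fully
connected trunk was chosen over a strided convolutional one: at the
package's box sizes the pooling achieves the same receptive-field
reduction, and the identity start — the property that actually matters
for avoiding early pose/shape entanglement amplification — is
preserved; tanh units were chosen because ReLU trunks can die wholesale
under aggressive adaptive optimization, which silently makes the
deformation image-independent. The gradient path into the encoder runs
through the spatial gradient of the scalar field at the bent points
(computed analytically by the interpolation kernels), through the
trilinear scatter onto the canonical lattice, and back through the
trunk.

Two structural safeguards address an exact degeneracy of the joint
problem: any image-independent deformation can be absorbed into the
canonical density, so the loss is flat along that direction and
first-order optimizers drift along it without bound. The head output is
therefore squashed through `max_disp * tanh(raw / max_disp)`
(default 6 Å — the physical scale of domain motions; identity near
zero), the head bias is not trained, and a mild L2 penalty on the
per-image deformation (`hetero_penalty`, default 1e-3) provides a
restoring force toward the identity that image-specific, loss-reducing
deformation easily out-competes. In principle the coarseness of the
canonical lattice could be the only regularizer; at the package's
scaled problem sizes the explicit ridge proved necessary for stable
inference, and it is kept as a default rather than an option.

Training schedule: because the encoder's gradient signal is the field's
spatial gradient, it is meaningless while the field is still
near-uniform. The first `hetero_warmup` epochs (default 1) therefore
train the field homogeneously; the encoder joins afterwards.

For downstream analysis the package infers per-image fields in two
stages: the amortized prediction provides the warm start, and
`refine_fields()` then optimizes each image's field directly against
the frozen canonical density (AdamW on the rendering loss plus the same
ridge; images batched in chunks). Amortized inference alone needs each
image revisited many times before its field is informative — with only
hundreds of particles and a few epochs the shared encoder cannot get
there, while direct refinement separates the states cleanly; using
amortization to initialize a local per-image optimization is the
natural two-stage composition of the two inference modes. Per-image
fields are flattened, their pairwise cosine similarity matrix is
formed, and states are assigned by spectral clustering (symmetric
normalized Laplacian of the affinity `(S+1)/2`, top-k eigenvector
embedding, k-means with many restarts under a fixed seed). Cluster
labels are arbitrary up to permutation; `match_labels()` resolves them
against a reference before computing the confusion matrix and its
accuracy / sensitivity / specificity / precision.

## The simulator

The synthetic-data generator produces exactly the statistical structure
the losses assume: a pseudo-atomic bead model (mixture of isotropic 3D
Gaussians; real coordinates loadable from CSV) evaluated analytically on
the voxel lattice; Haar-uniform poses (quaternion sampling) with optional
uniform in-plane shifts; CTFs with defocus drawn uniformly from
8000–25000 Å, up to 500 Å astigmatism, 300 kV, Cs 2.7 mm, amplitude
contrast 0.1 — typical single-particle collection values; and per-pixel
i.i.d. Gaussian noise. Clean projections are rendered through the *same*
forward model used in training (the ground-truth volume wrapped as a
voxel field), which guarantees train/simulation consistency by
construction and is verified by a test.

The homogeneous operating point is `sigma = 3` with the bead amplitude
calibrated to a mean SNR of 0.05 (SNR is defined as the clean-image pixel
variance over `sigma^2`, reported per image and summarized as
mean ± sd). Calibration is closed-form: clean images scale linearly with
amplitude, so one pilot batch determines the rescaling. The two-state
heterogeneity fixture uses high signal (`sigma = 0.1`) and builds state B
from state A by rigidly rotating one bead cluster about its centroid
(60° about z) and shifting it 4 Å — a large discrete domain motion of the
kind coarse-grained two-state benchmarks exhibit; the resulting state
volumes correlate at about 0.7. Stacks and metadata are written as MRCS
plus a RELION-dialect STAR file (ZYZ Euler angles in degrees, origin
shifts in Angstrom, standard CTF labels, and a state-label column), and
both round-trip through the package's readers — numeric STAR fields are
printed with 17 significant digits so they round-trip bit-exactly.

What the simulator does *not* emulate: structural noise, ice and detector
effects, dose and motion blur, pose/CTF estimation error, and the
non-white noise statistics of real micrographs. Tests passing on this
generator therefore demonstrate the estimator's correctness and the
optimization's behaviour under the model's own assumptions, not
performance on empirical data.

## Validation

Fourier shell correlation uses unit-voxel-width shells of the rounded
integer frequency radius (DC in shell 0) and the standard normalized
cross-correlation per shell; the resolution readout is the first
threshold crossing, linearly interpolated between shells, capped at the
Nyquist resolution `2 * pixel_size`, with a flag when no crossing
occurs. Conventional thresholds: 0.5 against an independent reference,
0.143 between half-maps. `run_half_maps()` trains two fields on disjoint
halves and reports both the half-map FSC and, optionally, each half's
FSC to a reference — the latter is offered deliberately: representations
with strong shared inductive bias can inflate half-map FSC early in
training without agreeing with the true map, so half-map FSC alone
should not be trusted in that regime. No FSC masking or
phase-randomization corrections are applied. Real-space agreement is
measured as Pearson correlation over (optionally masked) voxels.

## Masking

Training can be restricted to a region by supplying a soft mask volume:
the mask is trilinearly interpolated at the grid points, points above the
cutoff (default 0 — thresholding is the only binarization step) are
retained, and the projection matrix simply drops the other columns.
Validating small masked regions with the FSC is confounded by the shared
sharp boundary, so masked experiments are evaluated with the real-space
correlation inside the mask instead.

## Optimization and reproducibility

AdamW throughout, learning rate 1e-2 for both the encoding parameters
(hash tables, voxel array) and the MLPs. Split rates with a slower
decoder were tried first and stall in the single-epoch regime — the
decoder must keep pace with the tables when each particle is seen once —
so a common 1e-2 is the default; the deformation encoder's rate and
weight decay are separately configurable. Default batch size 8; the
scaled-down protocols below use batch 2, which at a fixed render budget
doubles the number of optimizer steps per epoch. A configurable fraction
(default 5%) of particles is held out and the validation loss is
evaluated every 100 steps with jitter disabled. Every source of
randomness (initialization, batching, jitter, simulation) derives from
explicit seeds, and identical configs reproduce identical loss
trajectories bit-for-bit; checkpoints serialize the full field (config
plus parameters) and round-trip exactly.

## Scaled-down study protocols

The package's reference experiments are sized for a single CPU:

* **Homogeneous reconstruction**: 200 clean 32×32 particles of a
  24-bead phantom (box 40 Å, `n_z = 32`), hash size `2^14`, CC loss,
  one epoch at batch 2. The trained field's FSC-0.5 resolution against
  the ground-truth volume improves from ~21 Å at initialization to
  ~9 Å — the ≥2× improvement asserted by the acceptance suite.
* **Heterogeneity**: 200+200 two-state particles at `sigma = 0.1`
  (mobile cluster rotated 60° and shifted 6 Å; state volumes correlate
  at ~0.6), 24³ grid, one warm-up epoch plus two joint epochs, then
  per-image refinement; within-state versus between-state cosine
  similarity and spectral-clustering accuracy are the readouts.
* **Masking**: the same phantom trained inside a spherical sub-mask with
  three logged checkpoints; the in-mask real-space correlation must
  increase across checkpoints.

## Known limitations

* Poses and CTFs are consumed, never estimated; there is no ab initio
  mode.
* The FSC is uncorrected (no soft-edge masking or phase randomization).
* Amortized deformation inference alone is weak at small particle
  counts: the encoder's per-image fields only separate conformational
  states clearly after the per-image refinement stage. With tens of
  thousands of images and long training the amortized path would carry
  more of the burden.
* The BioEM loss's prior parameters (scale 1, offset 0, sd 10) are a
  documented convention; the original derivation leaves them open.
* Compositional (multi-body, occupancy) heterogeneity and mass-displacing
  deformation models are out of scope.
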