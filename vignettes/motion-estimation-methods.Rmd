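---
title: "Methods: single-projection real-time 4D-CBCT estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-projection real-time 4D-CBCT estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Image-guided radiotherapy of moving targets (lung SBRT in particular) needs
volumetric knowledge of the anatomy *during* treatment. A conventional
cone-beam CT requires a full gantry rotation and delivers one motion-blurred
static volume; a time-resolved 4D-CBCT from full projection sets is slow and
dose-expensive. `rt4dcbct` implements the alternative this package is built
around: estimate the entire moving volume in real time from a *single*
projection angle, by combining

1. a low-dimensional **PCA motion model** of the patient's respiratory
   deformation, built once from planning 4D-CT deformation vector fields
   (DVFs), and
2. a **convolutional LSTM (ConvLSTM)** that regresses the PCA coefficients of
   the current breathing state from a short sequence of consecutive
   projections, exploiting the temporal correlation that single-frame CNN
   regressors discard.

Once the coefficients \(q\) of the current frame are known, the phased volume
is recovered by warping the reference-phase volume with the synthesized DVF.

## Motion model

Each phase DVF (displacement of every voxel from the 0% reference phase, in
mm, pull-back convention) is flattened to a vector of length \(3N_{voxel}\).
Mean-centered PCA over the phase stack gives
\[
\mathrm{DVF}(i) \;\approx\; \bar d + \sum_{j=1}^{k} q_j(i)\, p_j ,
\]
with orthonormal eigen-fields \(p_j\) ordered by explained variance and
per-phase coefficients \(q_j(i)\). The package computes the decomposition by
thin SVD of the mean-centered \(3N \times P\) matrix (identical to the
covariance eigendecomposition at a fraction of the cost) and keeps the full
spectrum, so the cumulative "information curve" used to choose the truncation
order is always available. The default truncation is \(k = 3\): for
respiratory DVF stacks the first three components typically carry ~97% of the
variance, and the curve necessarily closes at 100% at \(P - 1\) components
for \(P\) mean-centered fields.

Why mean-centering: without an explicit mean term the basis must also encode
the average deformation, which mixes a rank-one offset into every component;
with it, the information curve of \(P\) phases closes exactly at \(P-1\)
components, which is the structure observed in practice.

## Synthetic 4D thorax phantom

Licensed anthropomorphic phantoms cannot ship with an open package, so the
generator builds an analytic stand-in that preserves exactly the statistical
structure the method depends on — smooth, low-rank, SI-dominant motion —
while remaining fully reproducible:

* Soft-edged ellipsoids for body (0.020 mm⁻¹), lungs (0.004), diaphragm
  (0.022) and a 10 mm-radius tumor (0.030), on a 64³ grid at 4 mm spacing by
  default (tests use 32³ at 8 mm).
* A primary displacement mode: peak excursion `max_displacement`
  (default LR/AP/SI = 1.2/3.6/12 mm, i.e. AP and LR at 30%/10% of SI),
  constant over the inferior thorax and decaying smoothly to zero at the
  lung apex.
* A raised-cosine breathing trace \(a_i = (1 - \cos 2\pi i/n)/2\) over
  \(n = 10\) phases, so phase 0 is the zero-amplitude reference. Ten phases
  is the conventional 4D-CT binning; it also makes the mean-centered phase
  stack close at 8 components.
* Eight smaller harmonic modes (hysteresis-like AP lag, chest-wall
  expansion, localized residual fields) with Fourier phase dependence.
  These are essential: a trace-scaled single mode would make all phase DVFs
  collinear (rank 1), which no registration-derived stack exhibits. The mode
  amplitudes were calibrated once so the resulting eigen-spectrum matches
  the canonical shape of respiratory DVF stacks — cumulative information
  ≈ 74 / 89 / 97% at 1 / 2 / 3 components — and are not tuned thereafter.

Every phase volume is the analytic reference scene evaluated at
\(x + d_i(x)\), so volumes and ground-truth DVFs are consistent by
construction: trilinear pull-back warping of the reference with \(d_i\)
reproduces phase \(i\) to NCC ≥ 0.99 on the grid interior (the residual is
interpolation error, not model error). Because all structures move with one
smooth, small-magnitude (hence injective) map, tumor-inside-lung containment
at the reference phase is preserved at every amplitude in \([0, 1.15]\).

What the phantom does *not* emulate: realistic CT texture and noise,
cardiac motion, sliding interfaces at the pleura, and breathing
irregularity beyond amplitude scaling. Pipeline results on the phantom
therefore demonstrate correctness and internal consistency of the method,
not clinical performance.

## Projection simulation

DRRs are exact radiological path integrals (Siddon incremental traversal,
piecewise-constant voxels) from the source to each detector pixel centre at
one fixed gantry angle. Geometry defaults are typical of linac CBCT — SAD
1000 mm, SDD 1500 mm, gantry 0° — with a 64 × 64 panel at 6 mm pitch in the
desk-scale study so the full phantom footprint is covered. A dense
ray-marching implementation is deliberately kept in the test suite as an
independent oracle rather than being the production path.

Quantum noise follows
\(I = \mathrm{Poisson}(I_0 e^{-p_n}) + \mathcal{N}(0, \sigma_e^2)\) with
\(I_0 = 10^5\) and \(\sigma_e^2 = 10\); the draw is clamped to one photon
(so the log stays defined) and converted back to the line-integral domain,
which is what the network consumes. Noise is injected in the intensity
domain because that is where both photon statistics and electronic noise
physically act.

The intensity-correction step that aligns simulated DRRs with measured
projections defaults to exact moment matching,
\((I - \bar I_{DRR})/\sigma_{DRR} \cdot \sigma_{Proj} + \bar I_{Proj}\),
which achieves the stated goal (removing the first- and second-moment
mismatch) exactly; the literal published variant, which reuses the pixel
value in place of the DRR mean and does not equalize moments, is available
as mode `"as-printed"` for comparison. In the fully synthetic study the
correction has nothing to correct — training DRRs and the online stream
come from the same simulator — so `run_experiment()` does not apply it; it
is part of the API for pipelines with externally measured projections.

## Network

Each ConvLSTM cell applies the standard gate equations with 3 × 3
convolutions (stride 1) in place of dense products:
\(i_t, f_t, o_t = \sigma(\cdot)\), \(G_t = \tanh(\cdot)\),
\(C_t = f_t \circ C_{t-1} + i_t \circ G_t\),
\(H_t = o_t \circ \tanh C_t\). Two stacked cell layers with 40 hidden
channels are the published ablation optimum and the package default; the
desk-scale study uses 8 channels. "Valid" padding is applied on every input
path (frame → layer 1, layer *l* → *l + 1*) while the recurrent path is
"same"-padded — a recurrent state that shrank every time step could not be
reused, so valid padding can only be meant between layers. The regression
head is one convolutional-pooling stage (3 × 3, stride 2 — a 2× down-
sampling, the pooling variant with the best convergence) followed by fully
connected layers of width 1024 and \(k\).

Training minimizes
\(\frac{1}{N}\sum_i \lVert w_{coeff} \circ (y_i - \hat y_i) \rVert^2\) with
\(w_{coeff} = (2/6, 1/6, 1/6)\), which deliberately concentrates accuracy on
the first, motion-dominant coefficient. Targets are standardized per
component before the loss — raw PCA coefficients span orders of magnitude
across components, and an unstandardized loss would let the first component
swamp the optimizer for the wrong reason (scale rather than weighting). For
the same reason the package reports per-component MAE in standardized units
when comparing accuracy *across* components. ADAM starts at learning rate
0.001 with step decay (×0.5 every 50 epochs; the schedule is configurable
since only "dynamic" is specified), batch size 8. Input frames are z-scored
per image. Gradients are clipped at global norm 5 for stability of short
desk-scale runs. The backward pass is hand-derived backpropagation through
time; it is verified against numerical differentiation in the test suite,
and all convolutions run as im2col gathers plus BLAS GEMM with C++ kernels
for the gather/scatter and gate fusion.

### Temporal sequence construction

The published pipeline trains on ~900 randomly sampled coefficient sets yet
feeds the network sequences of consecutive frames; random samples alone
carry no temporal order. The package resolves this by laying the samples
out along simulated breathing traces in coefficient space: the per-phase
coefficients are interpolated into a periodic trajectory, each trace draws
a scale factor uniformly from the ±15% expanded range (the stated
amplitude expansion) plus a small per-component jitter (2% of the
per-component range), consecutive frames are one phase bin apart, and
frames \(t-3 \dots t\) are labelled with the coefficients of frame \(t\).
Independent uniform per-component sampling over the expanded ranges — the
other defensible reading of "random sampling" — is retained as
`sample_coefficients()` for dataset generation outside the sequence
builder.

At test time, an online stream covering one full cycle (starting \(T - 1\)
frames before phase 0) is fed through a causal sliding window, so each
phase of the cycle is labelled by exactly one window and reconstruction
count equals `stream length - T + 1`. The held-out streams use scale 1 and
no jitter; since training scales are drawn continuously from
\([0.85, 1.15]\), the test trajectories are almost surely unseen. Test
projections receive the same noise model as training by default, matching
the simulated-measurement setting.

## Metrics

MAE, ZNCC, single-scale SSIM, PSNR, RMSE and MAPE. Two printed definitions
are deliberately regularized:

* The NCC formula as published has a dimensionally inconsistent denominator
  (a single sum and absolute values in the numerator); the standard
  zero-normalized cross correlation is implemented.
* The source text calls the metric "multi-scale SSIM" in prose but defines
  the single-scale index; the single-scale form with the standard Gaussian
  window (σ = 1.5, 11 × 11, \(C_1 = (0.01L)^2\), \(C_2 = (0.03L)^2\)) is
  implemented and matches scikit-image's reference implementation to 1e-4.
* MAPE guards its division with an ε-mask (\(|T| > 10^{-6}\max|T|\))
  because higher-order PCA coefficients cross zero.
* PSNR's `MAX` defaults to the reference image maximum (the printed values
  leave it unspecified); identical images report infinite PSNR, serialized
  as null in JSON.

Planar metrics evaluate the mid-coronal slice by default, the plane on
which published comparisons are tabulated; the slice index is the grid
midpoint since no slice is named.

## Desk-scale study and problem sizes

`desk_experiment_config()` freezes the configuration used by
`scripts/acceptance.R` and the acceptance tests: 64³ phantom at 4 mm, 10
phases, \(k = 3\), 300 noisy 64 × 64 DRR sequences (T = 4), ConvLSTM with 8
hidden channels / 2 cell layers, \(w_{coeff} = (2/6, 1/6, 1/6)\), batch 8,
15 epochs. These sizes are the package's chosen desk-scale operating point:
large enough for the network to learn the dominant coefficient to better
than 10% of its range and for reconstructions to exceed NCC 0.98 / SSIM
0.95 against ground truth, small enough to run on a single CPU in minutes.
The replicate-seed weighting study runs the same pipeline at 32³ / 32² with
150 sequences and 12 epochs. The published 200-epoch, 40-channel, ~900-DRR
GPU regime is reachable through the same configuration objects but is not
exercised by the tests.

## Numerical choices and degenerate inputs

* Trilinear warping fills out-of-domain samples with 0 and clips the tiny
  negative overshoots of interpolation on non-negative volumes.
* `fit_pca()` clamps `k` to the rank of the centered stack (with a
  warning); an all-identical stack is an error, as is coefficient sampling
  from motionless phases.
* Siddon traversal treats axis-parallel rays explicitly; rays missing the
  volume integrate to 0; the detector-footprint check warns rather than
  errors so deliberately cropped geometries remain usable.
* Noise clamping at one photon is logged; with \(I_0 = 10^5\) it only
  triggers beyond ~11.5 line-integral units (attenuation factor
  \(e^{-11.5}\)), far past any realistic thorax path.
* Forget-gate biases initialize to 1 (open memory path), other biases to 0,
  weights Glorot-uniform.
* All stages derive their RNG streams from one master seed; reports are
  bitwise reproducible on a fixed machine and BLAS.

## Known limitations

* The phantom's motion model is low-rank by construction, so PCA truncation
  error is intrinsically small; real registration-derived DVFs carry
  registration noise that would lower the information curve.
* One projection angle at gantry 0° is simulated; angle dependence is
  configurable but unstudied here.
* The ConvLSTM runs on CPU inside R; it is deliberately sized for
  correctness verification, not for the published training scale.
* No scatter, beam hardening, detector blur or bowtie filtering in the
  projector; noise is per-pixel independent.
* The convergence advantage reported for convolutional pooling over no
  pooling does not manifest at desk scale: with small fully connected heads
  and small sample counts, the un-pooled head fits as fast or faster. The
  package asserts the mechanism that is scale-independent — pooling cuts
  the head parameter count severalfold without degrading convergence — and
  leaves the epochs-to-threshold comparison to full-scale runs.
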