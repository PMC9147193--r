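---
title: "Unrolled Neumann-network reconstruction for parallel MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unrolled Neumann-network reconstruction for parallel MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neumannmri)
```

## The reconstruction problem

Accelerated parallel MRI acquires only a subset of the phase-encode lines of
k-space, simultaneously on several receiver coils. With `x` the unknown
magnitude image, `S` the complex per-coil sensitivity profiles, `F` the 2-D
Fourier transform and `M` the binary column-sampling operator, the
measurement model is

    y = A x + noise,      A = M ∘ F ∘ S.

Undersampling below the Nyquist rate aliases the zero-filled reconstruction;
the redundancy across coils (plus learned image priors) is what makes
recovery possible. The regularized least-squares estimate

    argmin_x  ½‖A x − y‖² + λ R(x)

can be approached by gradient iteration; expanding the normal-equation
inverse as a truncated Neumann series and accumulating the iterates gives
the unrolled *Neumann network*:

    x₀ = λ A^H y,
    x_j = x_{j-1} − λ A^H A x_{j-1} − λ R(x_{j-1}),
    x̂  = Σ_{j=0}^{N} x_j,

with `R` a trainable CNN. The package implements this image-domain form and
the *multi-domain network with sensitivity maps* (MDNNSM), which (i)
estimates `S` from the auto-calibration (ACS) lines with a CNN trained
jointly with the reconstruction, (ii) regularizes in the image domain and
the frequency domain in parallel,

    R(x) = CNN_I(x) + F⁻¹(CNN_F(F x)),

and (iii) carries the recursion and skip-connection accumulation on
multi-coil k-space:

    k₀ = λ M y,
    k_j = k_{j-1} − λ M k_{j-1} − F S R(S^H F⁻¹ k_{j-1}),
    k̂  = Σ k_j,    x̂ = RSS(F⁻¹ k̂),

where RSS is the root-sum-of-squares coil combination. `(I − λM)` is the
data-consistency block. Zero-filled and GRAPPA reconstructions are provided
as classical comparators, and NMSE/SSIM as the evaluation metrics.

The image-domain comparator network (`neumann_model()`) follows the
original map-free formulation: it runs the recursion on the multi-coil
image stack with `A = M ∘ F` per coil, regularizes all coils jointly as
channels, and combines with RSS at the end. Because `F⁻¹MF` is an
orthogonal projection, its initialization (with zero regularizers) is
exactly the zero-filled image, the same starting point as the multi-domain
model — so trained comparisons measure the architectures, not their
initializations. A SENSE-style variant with fixed ACS maps is available via
`use_maps = "acs"`.

## Reading the operators

Two printed conventions require interpretation, and the package takes a
documented stance on each:

* **The "inverse" of A.** The gradient iteration is written with `A⁻¹`, but
  `A` maps one image to many coil measurements and has no inverse. The only
  reading under which the update is a gradient step of the least-squares
  term is the adjoint `A^H = S^H ∘ F⁻¹ ∘ M`, and that is what
  `forward_adjoint()` computes. Similarly `S⁻¹` is realized as the
  conjugate-weighted combine `S^H(·) = Σ_c conj(S_c)·(·)`, which is the
  exact left inverse of `S` whenever the maps are pixelwise normalized
  (`Σ_c |S_c|² = 1`) — the normalization the sensitivity module enforces.
* **λ on the regularizer.** The series expansion carries `λR` inside the
  iterated operator while the printed recursion applies `R` unscaled. The
  package defaults to the series-consistent form (`lambda_on_reg = TRUE`)
  and exposes the literal form as a flag. All algebraic equivalence tests
  hold under either choice.
* **k₀ = λMy is kept as printed.** For multi-coil data, applying `F∘S` to
  the image-domain recursion would give `F S S^H F⁻¹ M F S x₀` rather than
  `λMy`; the pixelwise coil projection `S S^H` is not the identity, so the
  k-space recursion is an approximation of the image-domain one. It is
  implemented exactly as stated, and the single-coil case (`S ≡ 1`), where
  the two recursions agree term by term, is pinned by a test
  (`k̂ = F x̂` to 1e-8).

## Numerical conventions

* **Fourier transform:** centered (DC at the array center, shift before and
  after) and orthonormal (`1/√(rows·cols)`), so the transform is unitary,
  Parseval holds, and the adjoint equals the inverse. Arrays are
  `(rows, cols, coils)` with the undersampled phase-encode axis along
  columns.
* **Masks:** deterministic equi-spaced column lattices (every
  `acceleration`-th column from a 0-based `offset`) plus a centered,
  contiguous ACS block of `round(acs_fraction · num_cols)` columns
  (minimum 1). The study's parameter pairs are (2, 10%), (4, 8%), (8, 4%).
* **Complex data in networks:** a complex array with `C` coils is packed as
  `2C` real channels (all real parts, then all imaginary parts) and
  unpacked exactly; 16 coils become 32 channels.
* **Sensitivity maps:** `acs_lowres_maps()` zero-fills everything but the
  ACS block, applies a Hann window across the ACS columns (suppressing the
  Gibbs ringing a hard truncation leaves at object edges; for the
  normalized ratios this is exact whenever all coils share the anatomy),
  inverse transforms, and normalizes pixelwise by the RSS, zeroing pixels
  below 1e-3 of the peak RSS to keep the background from amplifying noise.
  `cnn_maps()` feeds the same ACS images through a U-Net *residually*
  (`input + net(input)`): with the zero-initialized final layer the learned
  estimator therefore starts at the classical estimate. This is a
  deliberate choice — a non-residual estimator with zero-initialized output
  yields all-zero maps, through which no reconstruction gradient flows, and
  joint training cannot begin.

## Networks and training

All three CNNs (`CNN_C`, `CNN_I`, `CNN_F`) share one U-Net architecture:
double 3×3 convolution + instance normalization + leaky ReLU (negative
slope 0.2) per level, 2×2 mean pooling down, nearest-neighbour upsampling
with skip concatenation up, and a zero-initialized 1×1 final convolution so
every regularization block is the zero map at initialization (block 0 is
then pure data consistency). Nearest-neighbour upsampling and
edge-replication padding (for sizes not divisible by `2^depth`) were chosen
over bilinear/reflect variants for their exact, simple adjoints; at the
scales used the difference is immaterial. Defaults: `N = 6` iteration
blocks, per-block trainable step sizes λ initialized to 1, block-specific
(unshared) regularizer parameters, with sharing available as a switch.

Because no automatic-differentiation framework is available to the package,
training runs on a small built-in reverse-mode engine (`with_tape()` /
`ad_backward()`): every operator in the recursion — convolutions, instance
norm, the unitary FFTs, masking, map application, RSS, and the SSIM loss —
registers a hand-derived vector-Jacobian product, and the whole unrolled
network is differentiated end to end (including through the map estimator
and its RSS normalization). The engine is validated against central finite
differences for every layer and for the complete models (relative error
≲ 1e-3 at ε = 1e-5, dominated by the finite-difference error itself).

The loss is `1 − SSIM` between the target magnitude image and the final
output magnitude, with a 7×7 uniform window and the target's maximum as the
dynamic range; the optimizer is Adam. The published recipe trains 50 epochs
on thousands of slices at learning rate 1e-4. The package's desk-scale
study profile — 64 training and 16 validation scenes of 64×64 pixels and 4
coils, 5 epochs, U-Nets of depth 2 and base width 4 — shrinks the number of
optimization steps by two orders of magnitude, and the learning rate is
raised to 1e-3 accordingly (the standard step-count/step-size trade-off);
the full-scale values remain the defaults of `train_config()`'s
documentation and are configurable everywhere. The evaluation convention
min-max rescales reference and reconstruction to [0, 4095] before NMSE/SSIM
(`evaluate()`); the loss itself uses physical scale.

## The synthetic acquisition generator

`phantom_scene()` emulates exactly the statistical structure the method
assumes: piecewise-smooth nonnegative anatomy (random ellipses inside a
fixed outline, clipped to [0, 1] — real-valued ground truth, like magnitude
T1 images), smooth complex coil profiles (Gaussian bumps centered on a
circle around the field of view with linear phase ramps, normalized to
pixelwise RSS 1), i.i.d. complex Gaussian k-space noise of per-entry
variance σ² (default σ = 0.005, a visually mild noise floor ~0.5% of the
DC-normalized signal), and the equi-spaced masks above. Everything is
seeded and reproducible. What it does *not* emulate: realistic MR contrast
physics, anatomy-scale structure, coil coupling, motion or ringing
artifacts, and non-Cartesian trajectories — so passing tests demonstrate
the correctness of the operators and the trainability of the architecture,
not clinical-grade image quality.

## Degenerate inputs and tie-breaks

Pixels with no coil signal get zero sensitivity (threshold 1e-3 of peak
RSS); RSS gradients at exact zeros are defined as 0. Non-finite iterates
abort reconstruction with the failing block index; non-finite losses abort
training with epoch/step diagnostics. GRAPPA calibration requires at least
as many ACS equations as kernel unknowns and reports the deficit otherwise;
reconstruction wraps rows circularly and treats out-of-grid source columns
as zeros. `evaluate()` refuses constant images (zero dynamic range).

## Known limitations

* The non-learned sensitivity comparator is the ACS low-resolution
  estimator, not a full eigen-decomposition (ESPIRiT) implementation.
* The k-space recursion inherits the printed approximation `k₀ = λMy`
  discussed above; with zero-initialized regularizers both unrolled models
  start at the zero-filled image, and at desk-scale step counts the trained
  quality is still far from converged (randomly initialized final layers
  were evaluated as an alternative and diverge badly — the random
  regularizer output compounds through the unrolled accumulation).
* Training is batch-size-1 stochastic descent on CPU; no augmentation,
  schedules, or mixed precision. At the desk-scale budget the multi-domain
  model clearly beats zero-filled and the map-free comparator, but the weak
  map-free comparator itself does not reliably beat zero-filled — it must
  learn coil-configuration-agnostic dealiasing (the simulator draws a fresh
  coil geometry per scene) in two orders of magnitude fewer steps than the
  published recipe. Published full-scale results show the same phenomenon
  for weak comparators at 4x (GRAPPA below zero-filled).
* HDF5 io shells out to the `h5py` of the `python` on `PATH`; without one,
  only the in-memory and simulator workflows are available.
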