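# neumannmri

Reconstruction of magnetic-resonance images from under-sampled multi-coil
k-space data with unrolled Neumann-series networks, in pure R.

Accelerated parallel MRI measures only a subset of phase-encode lines,
simultaneously on several receiver coils with spatially varying complex
sensitivities. With the forward operator `A = M ∘ F ∘ S` (sampling mask,
2-D Fourier transform, coil sensitivity maps), the acquisition is
`y = A x + ε`, and reconstruction solves the regularized least-squares
problem `argmin_x ½‖Ax − y‖² + λR(x)`. The package implements the truncated
Neumann-series unrolling of this problem,

```
x₀ = λ A^H y,   x_j = x_{j−1} − λ A^H A x_{j−1} − λ R(x_{j−1}),   x̂ = Σ_j x_j
```

with a CNN regularizer `R`, and the multi-domain variant with learned
sensitivity maps (MDNNSM) that estimates `S = CNN_C(F⁻¹ M_ACS y)` from the
auto-calibration lines, regularizes in image and frequency domains in
parallel (`R(x) = CNN_I(x) + F⁻¹ CNN_F(F x)`), and accumulates the
recursion on multi-coil k-space, ending with a root-sum-of-squares coil
combine. Around the core model it provides the classical machinery: exact
centered orthonormal FFT operators, equi-spaced sampling masks with
centered ACS blocks, ACS low-resolution sensitivity estimation, zero-filled
and GRAPPA baselines, NMSE/SSIM metrics with SSIM training loss, a
reverse-mode differentiation engine that trains the whole unrolled network
end to end on CPU, a synthetic multi-coil acquisition simulator, and
fastMRI-dialect HDF5 io. Intended users: MRI reconstruction researchers who
want a dependency-light, fully testable reference implementation of
unrolled reconstruction in R.

## Worked example

Simulate an 8-coil acquisition at 2× acceleration with a 25% ACS block and
compare classical reconstructions against the ground truth:

```r
library(neumannmri)

sc  <- phantom_scene(rows = 64, cols = 64, num_coils = 8,
                     acceleration = 2, acs_fraction = 0.25,
                     noise_sigma = 0, seed = 12)
acq <- simulate_acquisition(sc)

zf <- zero_filled(acq$y)          # aliased baseline
gr <- grappa(acq$y, acq$mask)     # autocalibrated k-space interpolation

round(c(zerofill = nmse(zf, sc$x), grappa = nmse(gr, sc$x)), 5)
#> zerofill   grappa
#>  0.01001  0.00016
```

GRAPPA removes essentially all of the 1% aliasing energy the zero-filled
image carries at 2×. Training the unrolled networks on simulated scenes
(4 coils, 4× acceleration, 8%-12.5% ACS) and evaluating held-out scenes:

```r
train_ds <- simulate_dataset(64, 64, 64, 4, acceleration = 4,
                             acs_fraction = 0.125, seed = 1)
val_ds   <- simulate_dataset(16, 64, 64, 4, acceleration = 4,
                             acs_fraction = 0.125, seed = 90001)
cfg <- train_config(lr = 1e-3, epochs = 5, seed = 0)

ck <- train(mdnnsm_model(num_coils = 4, seed = 0), train_ds, cfg, val_ds)
mean(sapply(val_ds, function(s)
  nmse(model_reconstruct(ck$model, s$y, s$mask), s$target)))
#> [1] 0.01769
```

against 0.03180 for the zero-filled baseline and 0.03242 for the map-free
image-domain Neumann comparator under the same five-epoch budget: the
learned sensitivity maps plus multi-domain regularization nearly halve the
error where the image-only unrolling has not yet separated from the
zero-filled input (at this abbreviated training budget the weak comparator
itself does not beat zero-filled; see the methods vignette). A command-line
surface wraps the same functions (`simulate | mask | recon | train | eval`):

```sh
Rscript inst/cli/neumannmri.R simulate --scenes 4 --coils 4 --size 64 --seed 0 --out s.h5
Rscript inst/cli/neumannmri.R recon --method zerofill --in s.h5 --out r.h5
Rscript inst/cli/neumannmri.R eval --pred r.h5 --report report.json
```

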