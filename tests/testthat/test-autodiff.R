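# Finite-difference validation of the reverse-mode engine: every layer used
# by the unrolled networks, plus the complex pipeline end to end.

test_that("layer gradients match central differences", {
  set.seed(1)
  checks <- list(
    conv = function() {
      W <- nn_param(array(rnorm(3 * 3 * 2 * 3, sd = 0.3), c(3, 3, 2, 3)))
      b <- nn_param(rnorm(3))
      x <- array(rnorm(10 * 8 * 2), c(10, 8, 2))
      wl <- array(rnorm(10 * 8 * 3), c(10, 8, 3))
      list(fn = function() ad_mean(ad_mul(ad_conv2d(x, W, b), wl)),
           params = list(W, b))
    },
    instnorm = function() {
      g <- nn_param(runif(3, 0.5, 1.5)); be <- nn_param(rnorm(3))
      xp <- nn_param(array(rnorm(6 * 6 * 3), c(6, 6, 3)))
      wl <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
      list(fn = function() ad_mean(ad_mul(ad_instnorm(xp, g, be), wl)),
           params = list(xp, g, be))
    },
    pool_up = function() {
      xp <- nn_param(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
      wl <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
      list(fn = function() ad_mean(ad_mul(ad_up2(ad_pool2(xp)), wl)),
           params = list(xp))
    },
    pad_crop = function() {
      xp <- nn_param(array(rnorm(7 * 5 * 2), c(7, 5, 2)))
      wl <- array(rnorm(7 * 5 * 2), c(7, 5, 2))
      list(fn = function() ad_mean(ad_mul(ad_crop(ad_pad_edge(xp, 3, 1), 7, 5), wl)),
           params = list(xp))
    })
  for (nm in names(checks)) {
    built <- checks[[nm]]()
    tr <- with_tape(built$fn)
    ad_backward(tr$tape, tr$out)
    for (p in built$params) {
      for (k in sample(length(p$value), min(4, length(p$value)))) {
        num <- num_grad_entry(built$fn, p, k)
        expect_lt(abs(num - p$grad[k]) / max(1e-6, abs(num)), 1e-3,
                  label = sprintf("%s grad entry", nm))
      }
      p$grad <- NULL
    }
  }
})

test_that("complex-pipeline gradients (fft, maps, rss, ssim) match central differences", {
  set.seed(2)
  S <- make_coil_maps(12, 12, 2, seed = 3)
  m <- make_equispaced_mask(12, 2, 0.25)
  target <- make_phantom(16, 16, 3, seed = 1)[1:12, 1:12] + 0.05
  # parameterize a complex image via its packed channels
  p <- nn_param(array(rnorm(12 * 12 * 2, sd = 0.5), c(12, 12, 2)))
  fn <- function() {
    x <- ad_ch2c(p, drop_coil = TRUE)
    k <- ad_apply_mask(ad_fft2c(ad_apply_maps(S, x)), m)
    xb <- ad_rss(ad_ifft2c(k))
    ssim_loss(xb, target, window = 5)
  }
  tr <- with_tape(fn)
  ad_backward(tr$tape, tr$out)
  for (k in sample(length(p$value), 8)) {
    num <- num_grad_entry(fn, p, k, eps = 1e-6)
    expect_lt(abs(num - p$grad[k]) / max(1e-6, abs(num)), 1e-3)
  }
})

test_that("whole-model gradients match central differences on a tiny scene", {
  acq <- tiny_acq(16, 16, coils = 2, accel = 2, acs = 0.25, seed = 5)
  model <- mdnnsm_model(2, num_blocks = 2,
                        reg_spec = unet_spec(2, 2, depth = 1, width = 3, zero_init_final = FALSE),
                        sens_spec = unet_spec(4, 4, depth = 1, width = 3, zero_init_final = FALSE),
                        seed = 11)
  params <- neumannmri:::model_params(model)
  fn <- function() ssim_loss(neumannmri:::model_forward(model, acq$y, acq$mask),
                             acq$scene$x)
  tr <- with_tape(fn)
  ad_backward(tr$tape, tr$out)
  expect_true(all(vapply(params, function(p) !is.null(p$grad), logical(1))))
  set.seed(6)
  errs <- sapply(round(seq(1, length(params), length.out = 8)), function(pi) {
    p <- params[[pi]]
    k <- sample(length(p$value), 1)
    num <- num_grad_entry(fn, p, k)
    abs(num - p$grad[k]) / max(1e-6, abs(num))
  })
  # the loss has kinks (leaky ReLU; the map-support threshold flips
  # background pixels discretely under sensitivity-network perturbations),
  # so central differences can cross a non-differentiability at isolated
  # entries: require near-exact agreement at most entries, bounded error at
  # the kink-crossing ones
  expect_lte(sort(errs)[6], 1e-3)
  expect_lt(max(errs), 5e-2)
})

test_that("tape-free evaluation and traced forward values agree", {
  acq <- tiny_acq(16, 16, coils = 2, accel = 2, acs = 0.25, seed = 7)
  model <- neumann_model(2, num_blocks = 2, seed = 2)
  plain <- model_reconstruct(model, acq$y, acq$mask)
  tr <- with_tape(function() neumannmri:::model_forward(model, acq$y, acq$mask))
  expect_identical(plain, ad_val(tr$out))
})
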