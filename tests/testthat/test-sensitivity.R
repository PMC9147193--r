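test_that("apply_maps / reduce_maps basic identities", {
  x <- matrix(random_cplx(64), 8)
  S1 <- array(1 + 0i, c(8, 8, 1))
  expect_equal(apply_maps(S1, x)[, , 1], x)
  expect_equal(reduce_maps(S1, apply_maps(S1, x)), x)
  expect_equal(apply_maps(S1, x * 0)[, , 1], x * 0)

  Spair <- array(0i, c(1, 1, 2))
  Spair[1, 1, ] <- c(1, 1i)
  out <- apply_maps(Spair, matrix(1 + 0i, 1, 1))
  expect_equal(as.vector(out), c(1 + 0i, 1i))
  expect_error(apply_maps(Spair, matrix(0i, 2, 2)), "mismatch")
})

test_that("reduce_maps is the adjoint of apply_maps and its left inverse when normalized", {
  for (seed in 1:10) {
    set.seed(seed)
    S <- make_coil_maps(8, 8, 3, seed = seed)
    x <- matrix(random_cplx(64), 8)
    z <- random_cplx_array(8, 8, 3)
    lhs <- sum(Conj(z) * apply_maps(S, x))          # <Sx, z>
    rhs <- sum(Conj(reduce_maps(S, z)) * x)         # <x, S^H z>
    expect_lt(Mod(lhs - rhs), 1e-8)
    expect_lt(max(Mod(reduce_maps(S, apply_maps(S, x)) - x)), 1e-10)
  }
})

test_that("acs_lowres_maps recovers constant maps up to a pixelwise phase", {
  C <- 4
  S <- array(complex(real = 1 / sqrt(C)), c(16, 16, C))
  x <- make_phantom(16, 16, 4, seed = 3) + 0.1   # strictly positive support
  m <- make_equispaced_mask(16, 2, 0.25)
  y <- apply_mask(fft2c(S * as.vector(x)), m)
  est <- acs_lowres_maps(y, m)
  expect_equal(Mod(est[, , 1]), matrix(1 / sqrt(C), 16, 16), tolerance = 1e-8)
  # all coils share the truncation phase, so ratios match the true ratios (= 1)
  expect_lt(max(Mod(est[, , 2] / est[, , 1] - 1)), 1e-8)
})

test_that("acs_lowres_maps output is RSS-normalized and scale invariant", {
  acq <- tiny_acq(32, 32, coils = 4, accel = 4, acs = 0.25, seed = 8)
  est <- acs_lowres_maps(acq$y, acq$mask)
  r <- rss_combine(est)
  expect_true(all(abs(r[r > 0] - 1) < 1e-6))
  est2 <- acs_lowres_maps(37.5 * acq$y, acq$mask)
  expect_equal(est, est2, tolerance = 1e-10)
  expect_error(acs_lowres_maps(acq$y, unclass(acq$mask)), "sampling_mask")
})

test_that("ACS estimate of smooth simulated maps is accurate inside the support", {
  sc <- phantom_scene(64, 64, 4, acceleration = 4, acs_fraction = 0.25,
                      noise_sigma = 0, seed = 17)
  acq <- simulate_acquisition(sc)
  est <- acs_lowres_maps(acq$y, acq$mask)
  support <- sc$x > 0.1
  err <- abs(Mod(est) - Mod(sc$maps))
  for (cc in 1:4) expect_lt(max(err[, , cc][support]), 0.05)
})

test_that("cnn_maps with the identity estimator reduces to acs_lowres_maps", {
  acq <- tiny_acq(32, 32, coils = 3, accel = 2, acs = 0.25, seed = 4)
  a <- acs_lowres_maps(acq$y, acq$mask)
  b <- cnn_maps(acq$y, acq$mask, net = NULL)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cnn_maps output always satisfies the normalization bound", {
  acq <- tiny_acq(32, 32, coils = 2, accel = 2, acs = 0.25, seed = 6)
  net <- with_seed(3, unet_init(unet_spec(4, 4, depth = 1, width = 4,
                                          zero_init_final = FALSE)))
  est <- cnn_maps(acq$y, acq$mask, net)
  r2 <- rss_combine(est)^2
  expect_lte(max(r2), 1 + 1e-6)
  # per-coil estimator mode also normalizes
  net2 <- with_seed(4, unet_init(unet_spec(2, 2, depth = 1, width = 4,
                                           zero_init_final = FALSE)))
  est2 <- cnn_maps(acq$y, acq$mask, net2, per_coil = TRUE)
  expect_lte(max(rss_combine(est2)^2), 1 + 1e-6)
  expect_error(cnn_maps(acq$y, acq$mask, net2), "channels")
})
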