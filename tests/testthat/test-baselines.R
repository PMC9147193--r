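test_that("zero-filled reconstruction basics", {
  acq <- tiny_acq(32, 32, coils = 4, accel = 1, acs = 0.25, seed = 1)
  expect_lt(max(abs(zero_filled(acq$y_full) - acq$x)), 1e-10)
  expect_equal(zero_filled(array(0i, c(8, 8, 2))), matrix(0, 8, 8))
  under <- tiny_acq(32, 32, coils = 4, accel = 4, acs = 0.125, seed = 2)
  expect_gt(nmse(zero_filled(under$y), under$x), 0)
})

test_that("calibration recovers a planted kernel", {
  C <- 3; accel <- 2
  set.seed(21)
  W <- list(matrix(random_cplx(C * 20 * C), C * 20, C) * 0.2)
  y <- planted_kspace(24, 24, C, accel, W)
  kern <- grappa_calibrate(y, accel, 5:20, damping = 0)
  expect_lt(max(Mod(kern$weights[[1]] - W[[1]])), 1e-6)
  # damping 0 equals plain least squares; tiny damping changes little
  kern2 <- grappa_calibrate(y, accel, 5:20, damping = 1e-12)
  expect_lt(max(Mod(kern2$weights[[1]] - W[[1]])), 1e-6)
})

test_that("calibration stays consistent as nested ACS regions grow", {
  C <- 2; accel <- 2
  set.seed(22)
  W <- list(matrix(random_cplx(C * 20 * C), C * 20, C) * 0.2)
  y <- planted_kspace(24, 32, C, accel, W, seed = 3)
  for (acs in list(9:24, 7:26, 5:28)) {
    kern <- grappa_calibrate(y, accel, acs, damping = 0)
    expect_lt(max(Mod(kern$weights[[1]] - W[[1]])), 1e-6)
  }
})

test_that("duplicated coils give symmetric kernel weights", {
  C <- 2; accel <- 2
  set.seed(23)
  y1 <- planted_kspace(24, 24, 1, accel,
                       list(matrix(random_cplx(20), 20, 1) * 0.3), seed = 5)
  ydup <- array(0i, c(24, 24, 2))
  ydup[, , 1] <- y1[, , 1]
  ydup[, , 2] <- y1[, , 1]
  kern <- grappa_calibrate(ydup, accel, 5:20, damping = 1e-6)
  Wd <- kern$weights[[1]]
  # source blocks of coil 1 and coil 2 are interchangeable: the ridge
  # solution distributes weight symmetrically across the duplicates
  idx1 <- seq(1, nrow(Wd), by = 2)
  idx2 <- seq(2, nrow(Wd), by = 2)
  expect_lt(max(Mod(Wd[idx1, ] - Wd[idx2, ])), 1e-6)
  expect_lt(max(Mod(Wd[, 1] - Wd[, 2])), 1e-6)
})

test_that("calibration errors out when the ACS cannot support the system", {
  acq <- tiny_acq(16, 16, coils = 2, accel = 2, acs = 0.25, seed = 3)
  expect_error(grappa_calibrate(acq$y_full, 2, 7:9), "ACS too small")
})

test_that("GRAPPA reconstructs noiseless 2x data accurately and preserves samples", {
  sc <- phantom_scene(64, 64, 8, acceleration = 2, acs_fraction = 0.25,
                      noise_sigma = 0, seed = 12)
  acq <- simulate_acquisition(sc)
  kern <- grappa_calibrate(acq$y, 2, seq(acq$mask$acs_start, acq$mask$acs_end))
  kfull <- grappa_reconstruct(acq$y, acq$mask, kern, return_kspace = TRUE)
  expect_identical(kfull[, acq$mask$sampled, ], acq$y[, acq$mask$sampled, ])
  x <- grappa_reconstruct(acq$y, acq$mask, kern)
  expect_lt(nmse(x, sc$x), 0.01)
  expect_lt(nmse(x, sc$x), nmse(zero_filled(acq$y), sc$x))
})

test_that("fully sampled input passes through GRAPPA unchanged", {
  acq <- tiny_acq(24, 24, coils = 2, accel = 2, acs = 0.25, seed = 4)
  kern <- grappa_calibrate(acq$y_full, 2, 5:20)
  full_mask <- make_equispaced_mask(24, 1, 0.25)
  full_mask$acceleration <- 2L   # kernel geometry check only
  expect_equal(grappa_reconstruct(acq$y_full, full_mask, kern),
               zero_filled(acq$y_full), tolerance = 1e-12)
  expect_error(grappa_reconstruct(acq$y, acq$mask,
                                  structure(list(accel = 4L), class = "grappa_kernel")),
               "mismatch")
})
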