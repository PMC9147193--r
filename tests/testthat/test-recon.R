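test_that("forward operator reduces to fft2c/ifft2c in the trivial model", {
  set.seed(1)
  m <- make_equispaced_mask(8, 1, 0.5)
  A <- forward_model(m, NULL)
  x <- matrix(random_cplx(64), 8)
  expect_equal(forward_apply(A, x)[, , 1], fft2c(x), tolerance = 1e-12)
  y <- random_cplx_array(8, 8, 1)
  expect_equal(forward_adjoint(A, y), ifft2c(y[, , 1]), tolerance = 1e-12)
  expect_equal(forward_apply(A, x * 0), array(0i, c(8, 8, 1)))
  # A^H A = I for full sampling with normalized maps
  S <- make_coil_maps(8, 8, 3, seed = 2)
  Af <- forward_model(m, S)
  expect_lt(max(Mod(forward_adjoint(Af, forward_apply(Af, x)) - x)), 1e-10)
})

test_that("forward and adjoint satisfy the inner-product identity", {
  for (seed in 1:100) {
    set.seed(seed)
    C <- sample(1:4, 1)
    m <- make_equispaced_mask(8, sample(c(2L, 4L), 1), 0.25)
    S <- if (C == 1 && seed %% 2 == 0) NULL else make_coil_maps(8, 8, C, seed = seed)
    A <- forward_model(m, S)
    x <- matrix(random_cplx(64), 8)
    y <- random_cplx_array(8, 8, if (is.null(S)) 1 else C)
    lhs <- sum(Conj(y) * forward_apply(A, x))
    rhs <- sum(Conj(forward_adjoint(A, y)) * x)
    expect_lt(Mod(lhs - rhs), 1e-8)
  }
})

test_that("full-mask lambda=1 zero-regularizer recursion recovers exactly", {
  acq <- tiny_acq(16, 16, coils = 3, accel = 1, acs = 0.25, seed = 9)
  A <- forward_model(acq$mask, acq$maps)
  out <- neumann_reconstruct(acq$y, A, neumann_config(num_blocks = 5),
                             keep_iterates = TRUE)
  expect_lt(max(Mod(out$xhat - acq$x)), 1e-12)
  for (j in 2:6) expect_lt(max(Mod(out$iterates[[j]])), 1e-12)
})

test_that("full-mask lambda=0.5 matches the geometric-series closed form", {
  acq <- tiny_acq(16, 16, coils = 2, accel = 1, acs = 0.25, seed = 10)
  A <- forward_model(acq$mask, acq$maps)
  for (N in 0:6) {
    cfg <- neumann_config(num_blocks = N, lambdas = rep(0.5, N + 1))
    xh <- neumann_reconstruct(acq$y, A, cfg)
    expect_lt(max(Mod(xh - (1 - 0.5^(N + 1)) * acq$x)), 1e-10)
  }
})

test_that("long zero-regularizer recursion matches the dense pseudoinverse", {
  set.seed(2)
  S <- make_coil_maps(8, 8, 2, seed = 2)
  m <- make_equispaced_mask(8, 2, 0.25)
  A <- forward_model(m, S)
  x <- matrix(runif(64), 8)
  y <- forward_apply(A, x)
  Amat <- matrix(0i, 128, 64)
  for (j in 1:64) {
    e <- matrix(0i, 8, 8); e[j] <- 1
    Amat[, j] <- as.vector(forward_apply(A, e))
  }
  xls <- MASS::ginv(Amat) %*% as.vector(y)     # minimum-norm least squares
  lam <- 1 / max(svd(Amat)$d)^2                # below 2 / ||A^H A||
  cfg <- neumann_config(num_blocks = 200, lambdas = rep(lam, 201))
  xh <- neumann_reconstruct(y, A, cfg)
  rel <- sqrt(sum(Mod(as.vector(xh) - xls)^2) / sum(Mod(xls)^2))
  expect_lt(rel, 1e-4)
})

test_that("zero-regularizer reconstruction is linear in the data", {
  set.seed(3)
  m <- make_equispaced_mask(16, 4, 0.25)
  S <- make_coil_maps(16, 16, 3, seed = 5)
  A <- forward_model(m, S)
  cfg <- neumann_config(num_blocks = 4, lambdas = rep(0.7, 5))
  y1 <- random_cplx_array(16, 16, 3)
  y2 <- random_cplx_array(16, 16, 3)
  a <- 1.7 - 0.3i; b <- -0.4 + 2i
  lhs <- neumann_reconstruct(a * y1 + b * y2, A, cfg)
  rhs <- a * neumann_reconstruct(y1, A, cfg) + b * neumann_reconstruct(y2, A, cfg)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-8)
})

test_that("k-space recursion equals the Fourier transform of the image recursion for one coil", {
  acq <- tiny_acq(16, 16, coils = 1, accel = 2, acs = 0.25, seed = 6)
  A <- forward_model(acq$mask, NULL)
  set.seed(10)
  K <- matrix(random_cplx(256), 16) * 0.05
  Rfix <- regularizer("image_only", image = function(z) 0.1 * z + K * mean(Mod(z)))
  for (lam_on in c(TRUE, FALSE)) {
    cfgI <- neumann_config(3, rep(0.8, 4), Rfix, "image", lambda_on_reg = lam_on)
    cfgK <- neumann_config(3, rep(0.8, 4), Rfix, "kspace", lambda_on_reg = lam_on)
    xi <- neumann_reconstruct(acq$y, A, cfgI)
    kk <- mdnnsm_reconstruct(acq$y, A, cfgK, keep_iterates = TRUE)
    expect_lt(max(Mod(kk$khat[, , 1] - fft2c(xi))), 1e-8)
  }
})

test_that("k-space recursion degenerate cases", {
  acq <- tiny_acq(16, 16, coils = 2, accel = 2, acs = 0.25, seed = 7)
  A <- forward_model(acq$mask, acq$maps)
  # N = 0: lambda-scaled zero-filled reconstruction
  for (lam in c(1, 0.5)) {
    cfg0 <- neumann_config(0, lambdas = lam, accumulate_domain = "kspace")
    expect_equal(mdnnsm_reconstruct(acq$y, A, cfg0),
                 rss_combine(ifft2c(lam * apply_mask(acq$y, acq$mask))),
                 tolerance = 1e-12)
  }
  # full mask, lambda = 1: k_j = 0 for j >= 1, xhat = RSS(ifft(y))
  full <- tiny_acq(16, 16, coils = 2, accel = 1, acs = 0.25, seed = 8)
  Af <- forward_model(full$mask, full$maps)
  out <- mdnnsm_reconstruct(full$y, Af, neumann_config(4, accumulate_domain = "kspace"),
                            keep_iterates = TRUE)
  for (j in 2:5) expect_lt(max(Mod(out$iterates[[j]])), 1e-12)
  expect_equal(out$xhat, rss_combine(ifft2c(full$y)), tolerance = 1e-12)
})

test_that("accumulators equal the re-summed recorded iterates bit-exactly", {
  acq <- tiny_acq(16, 16, coils = 2, accel = 2, acs = 0.25, seed = 12)
  A <- forward_model(acq$mask, acq$maps)
  cfg <- neumann_config(5, rep(0.9, 6), accumulate_domain = "kspace")
  out <- mdnnsm_reconstruct(acq$y, A, cfg, keep_iterates = TRUE)
  expect_identical(out$khat, Reduce(`+`, out$iterates))
  cfgI <- neumann_config(5, rep(0.9, 6))
  outI <- neumann_reconstruct(acq$y, A, cfgI, keep_iterates = TRUE)
  expect_identical(outI$xhat, Reduce(`+`, outI$iterates))
})

test_that("reconstruction magnitude is invariant under a global phase on the data", {
  acq <- tiny_acq(32, 32, coils = 3, accel = 2, acs = 0.25, seed = 13)
  th <- 1.1
  yr <- exp(1i * th) * acq$y
  cfg <- neumann_config(3, accumulate_domain = "kspace")
  x1 <- mdnnsm_reconstruct(acq$y, forward_model(acq$mask, acs_lowres_maps(acq$y, acq$mask)), cfg)
  x2 <- mdnnsm_reconstruct(yr, forward_model(acq$mask, acs_lowres_maps(yr, acq$mask)), cfg)
  expect_equal(x1, x2, tolerance = 1e-10)
})

test_that("data consistency block behaves as (I - lam M)", {
  set.seed(14)
  m <- make_equispaced_mask(8, 2, 0.25)
  k <- random_cplx_array(8, 8, 2)
  expect_identical(data_consistency_block(k, m, 0), k)
  dc1 <- data_consistency_block(k, m, 1)
  expect_true(all(dc1[, m$sampled, ] == 0))
  expect_identical(dc1[, !m$sampled, ], k[, !m$sampled, ])
  full <- make_equispaced_mask(8, 1, 0.5)
  expect_true(all(data_consistency_block(k, full, 1) == 0))
})

test_that("shared and unshared regularizer parameters agree at matched initialization", {
  acq <- tiny_acq(16, 16, coils = 2, accel = 2, acs = 0.25, seed = 15)
  shared <- mdnnsm_model(2, num_blocks = 3, share_params = TRUE, seed = 42)
  unshared <- mdnnsm_model(2, num_blocks = 3, share_params = FALSE, seed = 42)
  # copy the shared block into every unshared block
  sv <- lapply(collect_params(shared$regs), function(p) p$value)
  for (j in 1:3) {
    pj <- collect_params(unshared$regs[[j]])
    for (i in seq_along(pj)) pj[[i]]$value <- sv[[i]]
  }
  restore <- collect_params(unshared$sens_net)
  sv2 <- lapply(collect_params(shared$sens_net), function(p) p$value)
  for (i in seq_along(restore)) restore[[i]]$value <- sv2[[i]]
  expect_equal(model_reconstruct(shared, acq$y, acq$mask),
               model_reconstruct(unshared, acq$y, acq$mask), tolerance = 1e-12)
})
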