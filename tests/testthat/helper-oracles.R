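# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# Independent direct-formula SSIM: explicit double loop over uniform
# windows, kept deliberately naive and separate from the package
# implementation.
ssim_direct <- function(x, y, w, L, K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - w + 1L)) {
    for (j in seq_len(ncol(x) - w + 1L)) {
      xs <- x[i:(i + w - 1L), j:(j + w - 1L)]
      ys <- y[i:(i + w - 1L), j:(j + w - 1L)]
      mx <- mean(xs); my <- mean(ys)
      vx <- mean(xs^2) - mx^2
      vy <- mean(ys^2) - my^2
      cxy <- mean(xs * ys) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                      ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# Central-difference gradient of a scalar-valued closure w.r.t. one entry of
# one nn_param.
num_grad_entry <- function(loss_fn, param, k, eps = 1e-5) {
  v0 <- param$value[k]
  param$value[k] <- v0 + eps
  lp <- ad_val(loss_fn())
  param$value[k] <- v0 - eps
  lm <- ad_val(loss_fn())
  param$value[k] <- v0
  (lp - lm) / (2 * eps)
}

random_cplx <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))

random_cplx_array <- function(...) {
  d <- c(...)
  array(random_cplx(prod(d)), d)
}

# Small acquisition fixture shared across recon tests.
tiny_acq <- function(rows = 16, cols = 16, coils = 2, accel = 2,
                     acs = 0.25, sigma = 0, seed = 5) {
  sc <- phantom_scene(rows, cols, coils, accel, acs, noise_sigma = sigma, seed = seed)
  c(simulate_acquisition(sc), list(scene = sc))
}

# Build k-space exactly consistent with a planted kernel: random data on the
# equispaced lattice, missing columns defined by kernel interpolation.
planted_kspace <- function(nr, nc, C, accel, W, n_side = 2, k_rows = 5, seed = 13) {
  set.seed(seed)
  y <- array(0i, c(nr, nc, C))
  lat <- which(((seq_len(nc) - 1) %% accel) == 0)
  y[, lat, ] <- random_cplx(nr * length(lat) * C)
  ro <- seq_len(k_rows) - (k_rows + 1) %/% 2
  for (r in seq_len(accel - 1)) {
    offs <- neumannmri:::grappa_col_offsets(accel, r, n_side)
    for (tcol in setdiff(seq_len(nc), lat)) {
      if (((tcol - 1) %% accel) != r) next
      src <- matrix(0i, nr, C * k_rows * length(offs))
      col <- 0
      for (co in offs) for (dr in ro) {
        rp <- ((seq_len(nr) - 1 + dr) %% nr) + 1
        scol <- tcol + co
        for (cc in seq_len(C)) {
          col <- col + 1
          if (scol >= 1 && scol <= nc) src[, col] <- y[rp, scol, cc]
        }
      }
      y[, tcol, ] <- src %*% W[[r]]
    }
  }
  y
}

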