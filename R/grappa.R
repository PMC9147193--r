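# Classical comparators: zero-filled reconstruction and GRAPPA
# (autocalibrated k-space interpolation). GRAPPA fills each missing
# phase-encode column from neighbouring sampled columns in all coils with
# kernel weights calibrated on the fully sampled ACS block by damped least
# squares; acquired samples are never altered.

#' Zero-filled reconstruction
#'
#' Root sum of squares of the per-coil inverse Fourier transform of the
#' k-space data as given (missing entries stay zero). The standard aliased
#' baseline and the input of the image-domain U-Net comparator.
#'
#' @param y Complex `(rows, cols, coils)` k-space.
#' @return Nonnegative real matrix.
#' @export
zero_filled <- function(y) {
  if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
  rss_combine(ifft2c(y))
}

# Source column offsets relative to the target column for gap offset r
# (r = 1..accel-1 from the preceding lattice column): the 2*n_side lattice
# columns nearest the target.
grappa_col_offsets <- function(accel, r, n_side) {
  left <- -r - accel * (seq_len(n_side) - 1L)
  right <- (accel - r) + accel * (seq_len(n_side) - 1L)
  sort(c(left, right))
}

#' Calibrate GRAPPA kernel weights
#'
#' Solves, for each gap offset `r = 1..accel-1` and each target coil, the
#' damped least-squares system mapping source constellations (all coils,
#' `k_rows x 2*n_side` neighbours) to the target sample, with every
#' equation drawn from the fully sampled ACS block. Tikhonov damping is
#' `damping` times the mean diagonal of the normal matrix.
#'
#' @param y_acs Complex `(rows, cols, coils)` k-space containing a fully
#'   sampled contiguous column block.
#' @param accel Acceleration factor the kernel will be used at.
#' @param acs_cols Integer vector of fully sampled column indices (1-based,
#'   contiguous).
#' @param k_rows,n_side Kernel geometry: rows per source constellation and
#'   sampled source columns per side.
#' @param offset 0-based offset of the equispaced lattice the kernel will be
#'   applied to; calibration targets are restricted to ACS columns at gap
#'   offset `r` from that lattice, matching the interpolation geometry.
#' @param damping Relative Tikhonov damping (0 = plain least squares).
#' @return Object of class `grappa_kernel`: list of weight matrices
#'   (`n_src x coils`), one per gap offset, plus the geometry.
#' @export
grappa_calibrate <- function(y_acs, accel, acs_cols, k_rows = 5L, n_side = 2L,
                             offset = 0L, damping = 1e-4) {
  d <- dim(y_acs)
  nr <- d[1L]; C <- d[3L]
  accel <- as.integer(accel)
  if (accel < 2L) stop("acceleration must be >= 2 for GRAPPA")
  weights <- vector("list", accel - 1L)
  for (r in seq_len(accel - 1L)) {
    offs <- grappa_col_offsets(accel, r, n_side)
    targets <- acs_cols[((acs_cols - 1L - offset) %% accel) == r &
                        (acs_cols + min(offs)) >= min(acs_cols) &
                        (acs_cols + max(offs)) <= max(acs_cols)]
    n_src <- C * k_rows * length(offs)
    n_eq <- nr * length(targets)
    if (length(targets) == 0L || n_eq < n_src)
      stop(sprintf(
        "ACS too small to calibrate: need >= %d equations (ACS width >= %d columns), have %d",
        n_src, diff(range(offs)) + 1L + ceiling(n_src / nr), n_eq))
    ro <- seq_len(k_rows) - (k_rows + 1L) %/% 2L
    src <- matrix(0i, n_eq, n_src)
    tgt <- matrix(0i, n_eq, C)
    for (ti in seq_along(targets)) {
      tcol <- targets[ti]
      rows_idx <- (ti - 1L) * nr + seq_len(nr)
      col <- 0L
      for (co in offs) for (dr in ro) {
        rowperm <- ((seq_len(nr) - 1L + dr) %% nr) + 1L
        for (cc in seq_len(C)) {
          col <- col + 1L
          src[rows_idx, col] <- y_acs[rowperm, tcol + co, cc]
        }
      }
      tgt[rows_idx, ] <- y_acs[, tcol, ]
    }
    G <- Conj(t(src)) %*% src
    tau <- damping * Re(mean(diag(G)))
    W <- solve(G + tau * diag(nrow(G)), Conj(t(src)) %*% tgt)
    weights[[r]] <- W
  }
  structure(list(weights = weights, accel = accel, k_rows = as.integer(k_rows),
                 n_side = as.integer(n_side), num_coils = C),
            class = "grappa_kernel")
}

#' GRAPPA reconstruction
#'
#' Fills every missing k-space column by kernel interpolation from sampled
#' lattice columns (rows wrap circularly; source columns outside the grid
#' contribute zero), leaves acquired samples bit-identical, and returns the
#' root-sum-of-squares image of the completed k-space.
#'
#' @param y Complex `(rows, cols, coils)` under-sampled k-space.
#' @param m The `sampling_mask` (equi-spaced, same acceleration as the
#'   kernel).
#' @param kernel A [grappa_calibrate()] kernel.
#' @param return_kspace If `TRUE` return the completed k-space instead of
#'   the image.
#' @return Real image matrix (or completed complex k-space).
#' @export
grappa_reconstruct <- function(y, m, kernel, return_kspace = FALSE) {
  stopifnot(inherits(kernel, "grappa_kernel"), inherits(m, "sampling_mask"))
  if (m$acceleration != kernel$accel) stop("mask/kernel acceleration mismatch")
  d <- dim(y)
  nr <- d[1L]; nc <- d[2L]; C <- d[3L]
  if (C != kernel$num_coils) stop("coil count differs from calibration")
  accel <- kernel$accel
  ro <- seq_len(kernel$k_rows) - (kernel$k_rows + 1L) %/% 2L
  out <- y
  for (tcol in which(!m$sampled)) {
    r <- ((tcol - 1L) - m$offset) %% accel
    if (r == 0L) next   # lattice column, sampled by construction
    offs <- grappa_col_offsets(accel, r, kernel$n_side)
    n_src <- C * kernel$k_rows * length(offs)
    src <- matrix(0i, nr, n_src)
    col <- 0L
    for (co in offs) for (dr in ro) {
      rowperm <- ((seq_len(nr) - 1L + dr) %% nr) + 1L
      scol <- tcol + co
      for (cc in seq_len(C)) {
        col <- col + 1L
        if (scol >= 1L && scol <= nc) src[, col] <- y[rowperm, scol, cc]
      }
    }
    out[, tcol, ] <- src %*% kernel$weights[[r]]
  }
  if (return_kspace) out else rss_combine(ifft2c(out))
}

#' Calibrate-and-reconstruct convenience wrapper
#'
#' Calibrates the kernel on the mask's ACS block of `y` and reconstructs.
#'
#' @inheritParams grappa_reconstruct
#' @param ... Passed to [grappa_calibrate()].
#' @return Real image matrix.
#' @export
grappa <- function(y, m, ...) {
  kern <- grappa_calibrate(y, m$acceleration, seq(m$acs_start, m$acs_end),
                           offset = m$offset, ...)
  grappa_reconstruct(y, m, kern)
}
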