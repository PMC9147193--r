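# Equi-spaced (regular) undersampling masks with a centered, contiguous
# auto-calibration (ACS) block, and the ACS-only sub-mask operator.

#' Equi-spaced undersampling mask with a centered ACS block
#'
#' Builds the binary column-selection operator used for regular undersampling
#' of the phase-encode (column) axis: every `acceleration`-th column starting
#' at `offset` (0-based) is sampled, plus a contiguous block of
#' `round(acs_fraction * num_cols)` fully sampled low-frequency columns
#' centered on the spectrum (the auto-calibration signal, ACS). The study
#' parameter pairs are (acceleration, ACS fraction) = (2, 10\%), (4, 8\%)
#' and (8, 4\%). The mask is deterministic and idempotent as an operator.
#'
#' @param num_cols Number of k-space columns (phase-encode lines).
#' @param acceleration Integer acceleration factor, `1 <= acceleration <= num_cols`.
#' @param acs_fraction Fraction of columns in the ACS block, in `(0, 1]`;
#'   `acs_fraction * num_cols` must be at least 1.
#' @param offset 0-based offset of the equispaced lattice, `0 <= offset < acceleration`.
#' @return An object of class `sampling_mask`: a list with the logical
#'   `sampled` vector over columns plus the recorded geometry
#'   (`acceleration`, `acs_fraction`, `offset`, 1-based `acs_start`/`acs_end`).
#' @export
make_equispaced_mask <- function(num_cols, acceleration, acs_fraction, offset = 0L) {
  num_cols <- as.integer(num_cols)
  acceleration <- as.integer(acceleration)
  if (acceleration < 1L) stop("acceleration must be >= 1")
  if (acceleration > num_cols) stop("acceleration exceeds the number of columns")
  if (acs_fraction <= 0 || acs_fraction > 1) stop("acs_fraction must be in (0, 1]")
  if (acs_fraction * num_cols < 1) stop("acs_fraction * num_cols < 1: no ACS line")
  if (offset < 0L || offset >= acceleration) stop("offset must satisfy 0 <= offset < acceleration")
  n_acs <- max(1L, as.integer(round(acs_fraction * num_cols)))
  acs_start <- (num_cols - n_acs) %/% 2L + 1L     # 1-based
  acs_end <- acs_start + n_acs - 1L
  sampled <- ((seq_len(num_cols) - 1L) %% acceleration) == offset
  sampled[acs_start:acs_end] <- TRUE
  structure(
    list(num_cols = num_cols, sampled = sampled, acceleration = acceleration,
         acs_fraction = acs_fraction, offset = as.integer(offset),
         acs_start = acs_start, acs_end = acs_end),
    class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("sampling_mask: %d cols, acceleration %d, ACS cols %d..%d (%d lines), %d sampled\n",
              x$num_cols, x$acceleration, x$acs_start, x$acs_end,
              x$acs_end - x$acs_start + 1L, sum(x$sampled)))
  invisible(x)
}

#' Apply a sampling mask to k-space data
#'
#' Zeroes the unsampled columns; sampled columns are returned bit-identical.
#' Idempotent: applying the mask twice equals applying it once.
#'
#' @param k Complex matrix or `(rows, cols, coils)` array of k-space data.
#' @param m A [make_equispaced_mask()] object.
#' @return Masked array of the same shape.
#' @export
apply_mask <- function(k, m) {
  stopifnot(inherits(m, "sampling_mask"))
  d <- dim(k)
  if (is.null(d)) stop("k must be a matrix or 3-D array")
  if (d[2L] != m$num_cols) stop("column count of data and mask disagree")
  rows <- d[1L]
  keep <- rep(m$sampled, each = rows)   # recycles over the coil axis
  k * as.vector(keep)
}

#' Extract the ACS-only mask
#'
#' Returns a mask selecting only the contiguous centered ACS block (zeros
#' everywhere else), as used to build the sensitivity-estimation input
#' `F^-1(M_ACS y)`.
#'
#' @param m A `sampling_mask`.
#' @return A `sampling_mask` sampling exactly the ACS columns.
#' @export
acs_mask <- function(m) {
  stopifnot(inherits(m, "sampling_mask"))
  sampled <- rep(FALSE, m$num_cols)
  sampled[m$acs_start:m$acs_end] <- TRUE
  out <- m
  out$sampled <- sampled
  out
}

#' @rdname make_equispaced_mask
#' @param m A `sampling_mask`.
#' @return `mask_columns()`: integer vector of sampled column indices (1-based).
#' @export
mask_columns <- function(m) which(m$sampled)
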