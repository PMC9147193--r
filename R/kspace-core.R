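# Complex data model: centered orthonormal Fourier transforms, coil
# expansion/combination and real/imaginary channel packing. All arrays are
# column-major with layout (rows, cols) or (rows, cols, coils); the
# undersampled (phase-encode) axis is the column axis.

.fftshift_idx <- function(n) ((seq_len(n) - 1L - n %/% 2L) %% n) + 1L
.ifftshift_idx <- function(n) ((seq_len(n) - 1L + n %/% 2L) %% n) + 1L

.fft2c_mat <- function(m, inverse) {
  nr <- nrow(m)
  nc <- ncol(m)
  m <- m[.ifftshift_idx(nr), .ifftshift_idx(nc), drop = FALSE]
  m <- stats::fft(m, inverse = inverse)
  m[.fftshift_idx(nr), .fftshift_idx(nc), drop = FALSE] / sqrt(nr * nc)
}

.fft2c_nd <- function(x, inverse) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || length(d) > 3L)
    stop("expected a 2-D image or a (rows, cols, coils) array")
  if (length(d) == 2L) return(.fft2c_mat(x, inverse))
  out <- array(0i, d)
  for (cc in seq_len(d[3L])) out[, , cc] <- .fft2c_mat(x[, , cc], inverse)
  out
}

#' Centered orthonormal 2-D Fourier transform
#'
#' Applies the unitary discrete Fourier transform to the two spatial axes,
#' with the DC component at the array center (shift before and after the
#' transform) and `1/sqrt(rows * cols)` scaling, so that `fft2c()` and
#' [ifft2c()] are mutual inverses and isometries (Parseval) and the adjoint
#' of the transform equals its inverse. A constant image of value `c` on an
#' `n x n` grid maps to a spectrum whose single nonzero entry is `n * c` at
#' the center.
#'
#' @param x A complex (or real) matrix, or a 3-D `(rows, cols, coils)` array;
#'   the transform is applied per coil.
#' @return Complex array of the same shape.
#' @export
fft2c <- function(x) {
  if (!all(is.finite(x))) stop("non-finite input to fft2c")
  .fft2c_nd(x, inverse = FALSE)
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) .fft2c_nd(x, inverse = TRUE)

#' Root-sum-of-squares coil combination
#'
#' Combines per-coil complex images into a single nonnegative real magnitude
#' image: the pixelwise Euclidean norm over the coil axis. A single coil
#' reduces to the elementwise magnitude. Invariant under per-coil global
#' phase rotations.
#'
#' @param imgs Complex `(rows, cols, coils)` array (a matrix is treated as a
#'   single coil).
#' @return Real nonnegative matrix.
#' @export
rss_combine <- function(imgs) {
  if (is.matrix(imgs)) return(Mod(imgs))
  d <- dim(imgs)
  if (length(d) != 3L || d[3L] < 1L) stop("need a (rows, cols, coils) array with >= 1 coil")
  sqrt(rowSums(Mod(imgs)^2, dims = 2L))
}

#' Real/imaginary channel packing
#'
#' Splits complex multi-coil data into real and imaginary channels and
#' concatenates them along the channel axis, so `C` complex coils become
#' `2 C` real channels (all real parts first, then all imaginary parts).
#' `unpack_channels()` is the exact inverse.
#'
#' @param z Complex matrix or `(rows, cols, coils)` array.
#' @return Real `(rows, cols, 2 * coils)` array.
#' @export
pack_channels <- function(z) {
  if (is.matrix(z)) dim(z) <- c(dim(z), 1L)
  d <- dim(z)
  if (length(d) != 3L) stop("expected (rows, cols, coils) complex data")
  array(c(Re(z), Im(z)), c(d[1L], d[2L], 2L * d[3L]))
}

#' @rdname pack_channels
#' @param t Real `(rows, cols, 2 * coils)` array of packed channels.
#' @export
unpack_channels <- function(t) {
  d <- dim(t)
  if (is.null(d) || length(d) != 3L) stop("expected a (rows, cols, channels) array")
  if (d[3L] %% 2L != 0L) stop("odd channel count: cannot unpack into complex coils")
  C <- d[3L] %/% 2L
  re <- t[, , seq_len(C), drop = FALSE]
  im <- t[, , C + seq_len(C), drop = FALSE]
  array(complex(real = re, imaginary = im), c(d[1L], d[2L], C))
}
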