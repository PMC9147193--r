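# The parallel-MRI forward operator A = M o F o S, the image-domain Neumann
# network recursion, and the multi-domain k-space recursion with
# skip-connection accumulation.
#
# The acquisition model is y = A x + noise with A = M o F o S. The
# regularized least-squares problem argmin 0.5 ||A x - y||^2 + lam R(x),
# solved by gradient iteration, expands as a truncated Neumann series
#   x_hat = sum_{j=0}^{N} (I - lam A^H A - lam R)^j (lam A^H y),
# realized recursively with x_0 = lam A^H y. The printed iteration applies
# A^{-1}; A is non-square, so the only reading under which the update is a
# gradient step is the adjoint A^H = S^H o F^{-1} o M, and that is what is
# implemented.

#' Forward model for parallel MRI
#'
#' @param mask A [make_equispaced_mask()] sampling mask.
#' @param maps Complex `(rows, cols, coils)` sensitivity maps (may be a tape
#'   node during training), or `NULL` for the single-coil model `A = M o F`.
#' @return Object of class `forward_model`.
#' @export
forward_model <- function(mask, maps = NULL) {
  stopifnot(inherits(mask, "sampling_mask"))
  structure(list(mask = mask, maps = maps), class = "forward_model")
}

#' Apply the forward operator `A x = M F S x`
#'
#' Without maps (`A$maps = NULL`) the model is `A = M o F` applied per
#' coil: `x` may then be a single image or a multi-coil image stack, and no
#' coil combination takes place (the map-free regime of the original
#' Neumann-network comparator).
#'
#' @param A A [forward_model()].
#' @param x Complex matrix (image), or a multi-coil stack in map-free mode.
#' @return Complex `(rows, cols, coils)` masked k-space.
#' @export
forward_apply <- function(A, x) {
  stopifnot(inherits(A, "forward_model"))
  mc <- if (!is.null(A$maps)) apply_maps(A$maps, x)
        else if (length(dim(ad_val(x))) == 3L) x
        else ad_expand_coil(x)
  ad_apply_mask(ad_fft2c(mc), A$mask)
}

#' Apply the adjoint operator `A^H y = S^H F^{-1} M y`
#'
#' Without maps this is the per-coil `F^{-1} M`; a single-coil input is
#' returned as a plain matrix, a multi-coil input as the coil stack.
#'
#' @param A A [forward_model()].
#' @param y Complex `(rows, cols, coils)` k-space.
#' @return Complex matrix (image), or a multi-coil stack in map-free mode.
#' @export
forward_adjoint <- function(A, y) {
  stopifnot(inherits(A, "forward_model"))
  imgs <- ad_ifft2c(ad_apply_mask(y, A$mask))
  if (!is.null(A$maps)) return(reduce_maps(A$maps, imgs))
  if (dim(ad_val(imgs))[3L] == 1L) ad_drop_coil(imgs) else imgs
}

# single-coil helpers: add/remove a unit coil axis
ad_expand_coil <- function(x) {
  xv <- ad_val(x)
  ad_op(array(xv, c(dim(xv), 1L)), list(x),
        function(g) list(array(g, dim(xv))))
}

ad_drop_coil <- function(z) {
  zv <- ad_val(z)
  if (length(dim(zv)) == 2L) return(z)
  if (dim(zv)[3L] != 1L) stop("expected a single-coil array")
  ad_op(array(zv, dim(zv)[1:2]), list(z),
        function(g) list(array(g, dim(zv))))
}

#' Unrolled-network configuration
#'
#' @param num_blocks Number of iteration blocks `N >= 0` (default 6).
#' @param lambdas Per-block step sizes: numeric vector (or list of
#'   [nn_param()]s when training) of length `num_blocks + 1`; the first entry
#'   scales the initial term `lam A^H y` (k-space: `lam M y`), the rest the
#'   data-consistency/regularizer updates. Initialized to 1 for all blocks.
#' @param regularizers A single [regularizer()] shared by all blocks, or a
#'   list of `num_blocks` block-specific regularizers (the unshared,
#'   default-performing configuration).
#' @param accumulate_domain `"image"` for the standard image-domain
#'   accumulation, `"kspace"` for the multi-domain k-space accumulation.
#' @param lambda_on_reg If `TRUE` (default) the regularizer term is also
#'   scaled by the block's lambda, consistent with the series expansion
#'   `(I - lam A^H A - lam R)^j`; `FALSE` reproduces the printed recursion
#'   literally (no lambda on `R`).
#' @return Object of class `neumann_config`.
#' @export
neumann_config <- function(num_blocks = 6L, lambdas = rep(1, num_blocks + 1L),
                           regularizers = regularizer("zero"),
                           accumulate_domain = c("image", "kspace"),
                           lambda_on_reg = TRUE) {
  accumulate_domain <- match.arg(accumulate_domain)
  num_blocks <- as.integer(num_blocks)
  if (num_blocks < 0L) stop("num_blocks must be >= 0")
  nl <- if (is.list(lambdas)) length(lambdas) else length(lambdas)
  if (nl != num_blocks + 1L) stop("need num_blocks + 1 lambdas")
  structure(list(num_blocks = num_blocks, lambdas = lambdas,
                 regularizers = regularizers,
                 accumulate_domain = accumulate_domain,
                 lambda_on_reg = isTRUE(lambda_on_reg)),
            class = "neumann_config")
}

get_lambda <- function(cfg, j) {
  if (is.list(cfg$lambdas)) cfg$lambdas[[j]] else cfg$lambdas[[j]]
}

get_regularizer <- function(cfg, j) {
  R <- cfg$regularizers
  if (inherits(R, "regularizer")) R else R[[j]]
}

check_finite_block <- function(x, j) {
  if (ad_tracing()) return(invisible(NULL))
  if (!all(is.finite(ad_val(x))))
    stop(sprintf("non-finite iterate at block %d", j))
  invisible(NULL)
}

#' Image-domain Neumann-network reconstruction
#'
#' Runs the truncated Neumann recursion
#' `x_0 = lam A^H y`, `x_j = x_{j-1} - lam A^H A x_{j-1} - [lam] R(x_{j-1})`
#' and returns the accumulated sum over `j = 0..N`. With the zero
#' regularizer this is the truncated Neumann series for the least-squares
#' normal equations (and converges to the minimum-norm solution as `N`
#' grows, for step sizes below `2 / ||A^H A||`). With a map-free
#' multi-coil model the iterates are coil stacks, the regularizer sees all
#' coils as channels, and callers combine the result with [rss_combine()]
#' (the original map-free comparator network).
#'
#' @param y Complex `(rows, cols, coils)` measured k-space.
#' @param A A [forward_model()].
#' @param cfg A [neumann_config()] with `accumulate_domain = "image"`.
#' @param keep_iterates If `TRUE`, also return the per-block iterates.
#' @return Complex matrix `x_hat`; with `keep_iterates`, a list with
#'   `xhat` and `iterates` (list of `x_j`).
#' @export
neumann_reconstruct <- function(y, A, cfg, keep_iterates = FALSE) {
  stopifnot(inherits(cfg, "neumann_config"))
  if (cfg$accumulate_domain != "image")
    stop("cfg$accumulate_domain must be 'image' for neumann_reconstruct")
  x <- ad_scale(forward_adjoint(A, y), get_lambda(cfg, 1L))
  check_finite_block(x, 0L)
  acc <- x
  iter <- if (keep_iterates) list(ad_val(x))
  N <- cfg$num_blocks
  for (j in seq_len(N)) {
    lam <- get_lambda(cfg, j + 1L)
    dc <- ad_scale(forward_adjoint(A, forward_apply(A, x)), lam)
    Rj <- get_regularizer(cfg, j)
    if (Rj$mode == "zero") {
      x <- ad_sub(x, dc)
    } else {
      r <- apply_regularizer(Rj, x)
      if (cfg$lambda_on_reg) r <- ad_scale(r, lam)
      x <- ad_sub(ad_sub(x, dc), r)
    }
    check_finite_block(x, j)
    acc <- ad_add(acc, x)
    if (keep_iterates) iter[[j + 1L]] <- ad_val(x)
  }
  if (keep_iterates) list(xhat = acc, iterates = iter) else acc
}

#' Multi-domain k-space reconstruction (MDNNSM recursion)
#'
#' The k-space form of the Neumann recursion, obtained by applying `F o S`
#' to the image-domain iteration so the accumulation happens on multi-coil
#' k-space data:
#' `k_0 = lam M y`,
#' `k_j = k_{j-1} - lam M k_{j-1} - F S R(S^H F^{-1} k_{j-1})`,
#' `k_hat = sum_j k_j`, and the output image is the root sum of squares of
#' the per-coil inverse transform of `k_hat`. `(I - lam M)` is the data
#' consistency block. The regularizer acts on the coil-combined image
#' `S^H F^{-1} k`, and is optionally scaled by lambda (see
#' [neumann_config()]).
#'
#' @param y Complex `(rows, cols, coils)` measured k-space.
#' @param A A [forward_model()] whose maps came from the sensitivity module
#'   (`NULL` maps = single-coil `S = 1`).
#' @param cfg A [neumann_config()] with `accumulate_domain = "kspace"`.
#' @param keep_iterates If `TRUE`, also return `khat` and per-block `k_j`.
#' @return Nonnegative real matrix `x_hat`; with `keep_iterates`, a list
#'   with `xhat`, `khat` and `iterates`.
#' @export
mdnnsm_reconstruct <- function(y, A, cfg, keep_iterates = FALSE) {
  stopifnot(inherits(cfg, "neumann_config"))
  if (cfg$accumulate_domain != "kspace")
    stop("cfg$accumulate_domain must be 'kspace' for mdnnsm_reconstruct")
  m <- A$mask
  S <- A$maps
  k <- ad_scale(ad_apply_mask(y, m), get_lambda(cfg, 1L))
  check_finite_block(k, 0L)
  acc <- k
  iter <- if (keep_iterates) list(ad_val(k))
  for (j in seq_len(cfg$num_blocks)) {
    lam <- get_lambda(cfg, j + 1L)
    kdc <- ad_sub(k, ad_scale(ad_apply_mask(k, m), lam))   # (I - lam M) k
    Rj <- get_regularizer(cfg, j)
    if (Rj$mode == "zero") {
      k <- kdc
    } else {
      ximg <- if (is.null(S)) ad_drop_coil(ad_ifft2c(k))
              else reduce_maps(S, ad_ifft2c(k))
      r <- apply_regularizer(Rj, ximg)
      if (cfg$lambda_on_reg) r <- ad_scale(r, lam)
      kr <- ad_fft2c(if (is.null(S)) ad_expand_coil(r) else apply_maps(S, r))
      k <- ad_sub(kdc, kr)
    }
    check_finite_block(k, j)
    acc <- ad_add(acc, k)
    if (keep_iterates) iter[[j + 1L]] <- ad_val(k)
  }
  xhat <- ad_rss(ad_ifft2c(acc))
  if (keep_iterates) list(xhat = xhat, khat = acc, iterates = iter) else xhat
}

#' Data consistency block `(I - lam M)`
#'
#' @param k Complex k-space array.
#' @param m Sampling mask.
#' @param lam Step size; `lam = 1` zeroes the sampled columns and preserves
#'   the unsampled ones.
#' @return Array of `k`'s shape.
#' @export
data_consistency_block <- function(k, m, lam) {
  ad_sub(k, ad_scale(ad_apply_mask(k, m), lam))
}
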