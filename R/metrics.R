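# Evaluation metrics: NMSE, SSIM with a uniform window (and a
# differentiable SSIM loss for training), and the evaluation-time
# normalization convention (reference and reconstruction min-max rescaled to
# [0, 4095] before metrics are computed).

#' Normalized mean squared error
#'
#' `||xhat - xref||^2 / ||xref||^2`. Not symmetric in its arguments: the
#' second argument is the reference that normalizes the error.
#'
#' @param xhat,xref Real arrays of identical shape; `xref` must not be
#'   identically zero.
#' @return Nonnegative scalar.
#' @export
nmse <- function(xhat, xref) {
  if (!identical(dim(xhat), dim(xref))) stop("shape mismatch")
  denom <- sum(xref^2)
  if (denom == 0) stop("reference image has zero norm")
  sum((xhat - xref)^2) / denom
}

# Mean over w x w windows, 'valid' positions only, via integral images.
box_mean <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x)
  ii <- rbind(0, apply(x, 2L, cumsum))
  ii <- cbind(0, t(apply(ii, 1L, cumsum)))
  r0 <- seq_len(nr - w + 1L); c0 <- seq_len(nc - w + 1L)
  (ii[r0 + w, c0 + w, drop = FALSE] - ii[r0, c0 + w, drop = FALSE] -
     ii[r0 + w, c0, drop = FALSE] + ii[r0, c0, drop = FALSE]) / (w * w)
}

# Adjoint of box_mean: pad with w-1 zeros on all sides, then box-sum.
box_mean_adj <- function(g, w, nr, nc) {
  gp <- matrix(0, nr + w - 1L, nc + w - 1L)
  gp[(w - 1L) + seq_len(nrow(g)), (w - 1L) + seq_len(ncol(g))] <- g
  box_mean(gp, w) * 1   # same 1/w^2 scaling; output is nr x nc
}

ad_box_mean <- function(x, w) {
  xv <- ad_val(x)
  nr <- nrow(xv); nc <- ncol(xv)
  ad_op(box_mean(xv, w), list(x), function(g) list(box_mean_adj(g, w, nr, nc)))
}

ssim_core <- function(x, y, w, data_range, K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mx <- ad_box_mean(x, w)
  my <- ad_box_mean(y, w)
  sxx <- ad_sub(ad_box_mean(ad_mul(x, x), w), ad_mul(mx, mx))
  syy <- ad_sub(ad_box_mean(ad_mul(y, y), w), ad_mul(my, my))
  sxy <- ad_sub(ad_box_mean(ad_mul(x, y), w), ad_mul(mx, my))
  num <- ad_mul(ad_add(ad_const_mul(ad_mul(mx, my), 2), C1),
                ad_add(ad_const_mul(sxy, 2), C2))
  den <- ad_mul(ad_add(ad_add(ad_mul(mx, mx), ad_mul(my, my)), C1),
                ad_add(ad_add(sxx, syy), C2))
  ad_div(num, den)
}

#' Structural similarity index (uniform window)
#'
#' Mean local SSIM over all `window x window` positions (uniform, not
#' Gaussian, weighting; the convention of the fastMRI evaluation code).
#' Equals 1 exactly iff the images are identical.
#'
#' @param xhat,xref Real matrices of identical shape.
#' @param window Side of the square window (default 7); must not exceed
#'   either image dimension.
#' @param data_range Dynamic range `L` of the data (default: range of the
#'   reference).
#' @param K1,K2 Stabilization constants of the luminance/contrast terms.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(xhat, xref, window = 7L, data_range = NULL,
                 K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(xhat), dim(xref))) stop("shape mismatch")
  if (window > nrow(xref) || window > ncol(xref)) stop("window larger than image")
  if (is.null(data_range)) data_range <- diff(range(xref))
  if (data_range <= 0) stop("data_range must be positive")
  mean(ssim_core(xhat, xref, as.integer(window), data_range, K1, K2))
}

#' SSIM training loss
#'
#' `1 - SSIM(pred, target)`, differentiable in `pred` through the tape (the
#' loss used to train the unrolled networks, computed between the target and
#' the magnitude of the final output). The dynamic range is the target's
#' maximum by default (physical scale; the 0-4095 display normalization is
#' an evaluation-time convention only and is not applied in the loss).
#'
#' @param pred Real matrix or tape node (magnitude/RSS output).
#' @param target Real matrix (constant).
#' @param window Uniform window side.
#' @param data_range Dynamic range (default `max(target)`).
#' @return Scalar (or scalar node) in `[0, 2]`.
#' @export
ssim_loss <- function(pred, target, window = 7L, data_range = NULL) {
  pv <- ad_val(pred)
  if (!identical(dim(pv), dim(target))) stop("shape mismatch")
  if (is.null(data_range)) data_range <- max(target)
  s <- ad_mean(ssim_core(pred, target, as.integer(window), data_range))
  ad_sub(1, s)
}

#' Evaluate reconstructions against references
#'
#' Applies the evaluation normalization (each slice min-max rescaled to
#' `[0, 4095]`, reference and reconstruction independently) and reports
#' per-slice and mean NMSE/SSIM. Invariant to joint positive rescaling of
#' reconstruction and reference. Constant images (zero dynamic range) are an
#' error.
#'
#' @param pred,ref Real matrices, 3-D arrays `(rows, cols, slices)`, or
#'   lists of matrices.
#' @param method,acceleration,acs_fraction Labels recorded in the report.
#' @param window SSIM window.
#' @return Object of class `eval_report`: list with `per_slice` (data frame
#'   of `slice`, `nmse`, `ssim`), `mean_nmse`, `mean_ssim` and the labels.
#' @export
evaluate <- function(pred, ref, method = "", acceleration = NA_integer_,
                     acs_fraction = NA_real_, window = 7L) {
  as_list <- function(x) {
    if (is.list(x)) x
    else if (is.matrix(x)) list(x)
    else lapply(seq_len(dim(x)[3L]), function(i) x[, , i])
  }
  pl <- as_list(pred)
  rl <- as_list(ref)
  if (length(pl) != length(rl)) stop("slice counts differ")
  norm4095 <- function(img) {
    rg <- range(img)
    if (diff(rg) == 0) stop("constant image: zero dynamic range")
    (img - rg[1L]) / diff(rg) * 4095
  }
  rows <- lapply(seq_along(pl), function(i) {
    p <- norm4095(pl[[i]])
    r <- norm4095(rl[[i]])
    data.frame(slice = i, nmse = nmse(p, r),
               ssim = ssim(p, r, window = window, data_range = 4095))
  })
  per_slice <- do.call(rbind, rows)
  structure(list(method = method, acceleration = acceleration,
                 acs_fraction = acs_fraction, per_slice = per_slice,
                 mean_nmse = mean(per_slice$nmse),
                 mean_ssim = mean(per_slice$ssim)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %s (accel %s, ACS %s): mean NMSE %.5f, mean SSIM %.4f over %d slice(s)\n",
              x$method, x$acceleration, x$acs_fraction,
              x$mean_nmse, x$mean_ssim, nrow(x$per_slice)))
  invisible(x)
}
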