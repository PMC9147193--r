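# Neural-network layers on (rows, cols, channels) real arrays, written as
# shift-and-GEMM convolutions so the heavy lifting is BLAS. Each layer has a
# hand-derived vector-Jacobian product registered with the autodiff tape.

# im2col index cache: for a (H, W) grid, k x k kernel and zero 'same'
# padding, the (H*W) x k^2 matrix of 1-based positions into the padded
# single-channel plane; channel offsets are added per call.
.conv_cache <- new.env(parent = emptyenv())

conv_idx <- function(H, W, cin, k) {
  key <- paste(H, W, cin, k, sep = "x")
  idx <- .conv_cache[[key]]
  if (!is.null(idx)) return(idx)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  di <- rep(seq_len(k), times = k)
  dj <- rep(seq_len(k), each = k)
  rowpos <- outer(ii - 1L, di - 1L, `+`) + 1L
  colpos <- outer(jj - 1L, dj - 1L, `+`) + 1L
  pos <- rowpos + (colpos - 1L) * Hp
  idx <- outer(as.vector(pos), (seq_len(cin) - 1L) * (Hp * Wp), `+`)
  # keep it a dim-less vector: an integer matrix with ndim(x) columns would
  # trigger R's matrix-indexing semantics in `xp[idx]`
  dim(idx) <- NULL
  storage.mode(idx) <- "integer"
  .conv_cache[[key]] <- idx
  idx
}

# Correlation of x (H, W, cin) with Wmat ((k*k*cin) x cout), zero 'same'
# padding, returning the (H*W) x cout result plus the gathered column
# matrix (needed for the weight gradient).
conv_gemm <- function(xv, Wmat, k, cout) {
  d <- dim(xv)
  H <- d[1L]; Wd <- d[2L]; cin <- d[3L]
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- Wd + 2L * p
  xp <- array(0, c(Hp, Wp, cin))
  xp[p + seq_len(H), p + seq_len(Wd), ] <- xv
  colm <- xp[conv_idx(H, Wd, cin, k)]
  dim(colm) <- c(H * Wd, k * k * cin)
  list(out = colm %*% Wmat, colm = colm)
}

# k x k convolution (odd k), stride 1, zero 'same' padding.
# W: (k, k, cin, cout) nn_param; b: length-cout nn_param.
ad_conv2d <- function(x, W, b) {
  xv <- ad_val(x); Wv <- ad_val(W); bv <- ad_val(b)
  d <- dim(xv)
  H <- d[1L]; Wd <- d[2L]; cin <- d[3L]
  k <- dim(Wv)[1L]
  cout <- dim(Wv)[4L]
  n <- H * Wd
  Wmat <- Wv
  dim(Wmat) <- c(k * k * cin, cout)
  cg <- conv_gemm(xv, Wmat, k, cout)
  val <- cg$out + rep(bv, each = n)
  dim(val) <- c(H, Wd, cout)
  ad_op(val, list(x, W, b), function(g) {
    gm <- g
    dim(gm) <- c(n, cout)
    dW <- crossprod(cg$colm, gm)
    dim(dW) <- c(k, k, cin, cout)
    db <- colSums(gm)
    # input gradient: correlate g with the spatially flipped, channel-swapped
    # kernel (the transpose of a zero-padded 'same' correlation).
    Wrot <- aperm(Wv[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dim(Wrot) <- c(k * k * cout, cin)
    dim(g) <- c(H, Wd, cout)
    dx <- conv_gemm(g, Wrot, k, cin)$out
    dim(dx) <- c(H, Wd, cin)
    list(dx, dW, db)
  })
}

# Leaky rectified linear unit with negative slope `slope`.
ad_lrelu <- function(x, slope = 0.2) {
  xv <- ad_val(x)
  mult <- (xv > 0) + slope * (xv <= 0)
  ad_op(xv * mult, list(x), function(g) list(g * mult))
}

# Instance normalization: per-channel standardization over the spatial axes
# with learnable gain/offset (gamma, beta: length-C nn_params).
ad_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x); gv <- ad_val(gamma); bv <- ad_val(beta)
  d <- dim(xv)
  n <- d[1L] * d[2L]
  C <- d[3L]
  xm <- xv
  dim(xm) <- c(n, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = n)
  val <- xhat * rep(gv, each = n) + rep(bv, each = n)
  dim(val) <- d
  ad_op(val, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(n, C)
    dbeta <- colSums(gm)
    dgamma <- colSums(gm * xhat)
    dxh <- gm * rep(gv, each = n)
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat)
    # dx = istd * (dxh - mean(dxh) - xhat * mean(dxh * xhat)), per channel
    dx <- (dxh - rep(m1, each = n) - xhat * rep(m2, each = n)) * rep(istd, each = n)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# 2x2 mean pooling (spatial dims must be even).
ad_pool2 <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  e1 <- seq(1L, W, 2L); e2 <- seq(2L, W, 2L)
  val <- (xv[o1, e1, , drop = FALSE] + xv[o2, e1, , drop = FALSE] +
          xv[o1, e2, , drop = FALSE] + xv[o2, e2, , drop = FALSE]) / 4
  ad_op(val, list(x), function(g) {
    dx <- array(0, d)
    gq <- g / 4
    dx[o1, e1, ] <- gq; dx[o2, e1, ] <- gq
    dx[o1, e2, ] <- gq; dx[o2, e2, ] <- gq
    list(dx)
  })
}

# Nearest-neighbour 2x upsampling.
ad_up2 <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]
  ri <- rep(seq_len(H), each = 2L)
  ci <- rep(seq_len(W), each = 2L)
  val <- xv[ri, ci, , drop = FALSE]
  ad_op(val, list(x), function(g) {
    o1 <- seq(1L, 2L * H, 2L); o2 <- seq(2L, 2L * H, 2L)
    e1 <- seq(1L, 2L * W, 2L); e2 <- seq(2L, 2L * W, 2L)
    list(g[o1, e1, , drop = FALSE] + g[o2, e1, , drop = FALSE] +
         g[o1, e2, , drop = FALSE] + g[o2, e2, , drop = FALSE])
  })
}

# Channel concatenation.
ad_concat <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  da <- dim(av); db <- dim(bv)
  val <- array(c(av, bv), c(da[1L], da[2L], da[3L] + db[3L]))
  ad_op(val, list(a, b), function(g) {
    list(g[, , seq_len(da[3L]), drop = FALSE],
         g[, , da[3L] + seq_len(db[3L]), drop = FALSE])
  })
}

# Edge-replication padding on the bottom/right to reach (H + pb, W + pr);
# crop is its exact inverse slice.
ad_pad_edge <- function(x, pb, pr) {
  xv <- ad_val(x)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]
  ir <- c(seq_len(H), rep(H, pb))
  jc <- c(seq_len(W), rep(W, pr))
  val <- xv[ir, jc, , drop = FALSE]
  ad_op(val, list(x), function(g) {
    dx <- g[seq_len(H), seq_len(W), , drop = FALSE]
    if (pb > 0) dx[H, , ] <- dx[H, , ] + apply(g[H + seq_len(pb), seq_len(W), , drop = FALSE], c(2, 3), sum)
    if (pr > 0) dx[, W, ] <- dx[, W, ] + apply(g[seq_len(H), W + seq_len(pr), , drop = FALSE], c(1, 3), sum)
    if (pb > 0 && pr > 0)
      dx[H, W, ] <- dx[H, W, ] + apply(g[H + seq_len(pb), W + seq_len(pr), , drop = FALSE], 3, sum)
    list(dx)
  })
}

ad_crop <- function(x, H, W) {
  xv <- ad_val(x)
  d <- dim(xv)
  val <- xv[seq_len(H), seq_len(W), , drop = FALSE]
  ad_op(val, list(x), function(g) {
    dx <- array(0, d)
    dx[seq_len(H), seq_len(W), ] <- g
    list(dx)
  })
}

# ---- optimizer ----

#' One Adam update over a parameter list
#'
#' Standard adaptive-moment update with bias correction; moment state lives
#' on each `nn_param` environment. Parameters with no accumulated gradient
#' are skipped. Gradients are cleared after the step.
#'
#' @param params Flat list of `nn_param`s (see [collect_params()]).
#' @param lr Learning rate.
#' @param t Step counter (1-based) for bias correction.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @export
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$adam_m)) {
      p$adam_m <- g * 0
      p$adam_v <- g * 0
    }
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * g
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * g^2
    mhat <- p$adam_m / (1 - beta1^t)
    vhat <- p$adam_v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}
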