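# U-Net built from the ad_* layers: per-level double convolution with
# instance normalization and leaky ReLU (slope 0.2), 2x2 mean pooling on the
# way down, nearest-neighbour upsampling with skip concatenation on the way
# up, and a final 1x1 convolution (zero-initialized by default so the
# network is the zero map at the start of training).

#' U-Net architecture specification
#'
#' @param in_ch,out_ch Input/output channel counts.
#' @param depth Number of down/up-sampling levels (spatial dims are padded to
#'   a multiple of `2^depth` with edge replication and cropped on output).
#' @param width Channel count of the first level; level `i` uses
#'   `width * 2^(i-1)`.
#' @param slope Negative slope of the leaky ReLU.
#' @param zero_init_final If `TRUE` (default) the final 1x1 convolution is
#'   zero-initialized, making the whole network the zero map at
#'   initialization (so an unrolled block starts as pure data consistency).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(in_ch = 2L, out_ch = in_ch, depth = 4L, width = 32L,
                      slope = 0.2, zero_init_final = TRUE) {
  structure(list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                 depth = as.integer(depth), width = as.integer(width),
                 slope = slope, zero_init_final = isTRUE(zero_init_final)),
            class = "unet_spec")
}

conv_init <- function(k, cin, cout, zero = FALSE) {
  W <- if (zero) array(0, c(k, k, cin, cout))
       else array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  c(k, k, cin, cout))
  list(W = nn_param(W), b = nn_param(rep(0, cout)))
}

block_init <- function(cin, cout) {
  list(conv1 = conv_init(3L, cin, cout),
       in1 = list(gamma = nn_param(rep(1, cout)), beta = nn_param(rep(0, cout))),
       conv2 = conv_init(3L, cout, cout),
       in2 = list(gamma = nn_param(rep(1, cout)), beta = nn_param(rep(0, cout))))
}

#' Initialize U-Net parameters
#'
#' He-normal convolution weights, unit-gain instance norms, and (by default)
#' a zero final layer. Uses the current RNG stream; seed with `set.seed()`
#' or [with_seed()] for reproducibility.
#'
#' @param spec A [unet_spec()].
#' @return List of class `unet` with `$spec` and nested `$params`.
#' @export
unet_init <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  w <- spec$width * 2L^(seq_len(spec$depth) - 1L)
  enc <- vector("list", spec$depth)
  cin <- spec$in_ch
  for (i in seq_len(spec$depth)) {
    enc[[i]] <- block_init(cin, w[i])
    cin <- w[i]
  }
  bottom <- block_init(cin, 2L * cin)
  dec <- vector("list", spec$depth)
  clow <- 2L * cin
  for (i in rev(seq_len(spec$depth))) {
    dec[[i]] <- block_init(clow + w[i], w[i])
    clow <- w[i]
  }
  final <- conv_init(1L, spec$width, spec$out_ch, zero = spec$zero_init_final)
  structure(list(spec = spec,
                 params = list(enc = enc, bottom = bottom, dec = dec, final = final)),
            class = "unet")
}

conv_block <- function(x, p, slope) {
  x <- ad_conv2d(x, p$conv1$W, p$conv1$b)
  x <- ad_instnorm(x, p$in1$gamma, p$in1$beta)
  x <- ad_lrelu(x, slope)
  x <- ad_conv2d(x, p$conv2$W, p$conv2$b)
  x <- ad_instnorm(x, p$in2$gamma, p$in2$beta)
  ad_lrelu(x, slope)
}

#' U-Net forward pass
#'
#' Shape-preserving: output has the input's spatial dims and the declared
#' `out_ch` channels. Works on plain arrays (inference) or inside a tape
#' (training).
#'
#' @param net A [unet_init()] model.
#' @param x Real `(rows, cols, in_ch)` array or tape node.
#' @return `(rows, cols, out_ch)` array or node.
#' @export
unet_forward <- function(net, x) {
  stopifnot(inherits(net, "unet"))
  sp <- net$spec
  pp <- net$params
  d <- dim(ad_val(x))
  if (d[3L] != sp$in_ch) stop(sprintf("expected %d input channels, got %d", sp$in_ch, d[3L]))
  mult <- 2L^sp$depth
  H <- d[1L]; W <- d[2L]
  pb <- (mult - H %% mult) %% mult
  pr <- (mult - W %% mult) %% mult
  if (pb > 0L || pr > 0L) x <- ad_pad_edge(x, pb, pr)
  skips <- vector("list", sp$depth)
  for (i in seq_len(sp$depth)) {
    x <- conv_block(x, pp$enc[[i]], sp$slope)
    skips[[i]] <- x
    x <- ad_pool2(x)
  }
  x <- conv_block(x, pp$bottom, sp$slope)
  for (i in rev(seq_len(sp$depth))) {
    x <- ad_up2(x)
    x <- ad_concat(x, skips[[i]])
    x <- conv_block(x, pp$dec[[i]], sp$slope)
  }
  x <- ad_conv2d(x, pp$final$W, pp$final$b)
  out <- x
  if (pb > 0L || pr > 0L) out <- ad_crop(out, H, W)
  v <- ad_val(out)
  if (!all(is.finite(v))) stop("non-finite U-Net output")
  out
}
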