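# CNN regularization block. The regularizer acts on the current combined
# complex image estimate; complex data reaches the networks as two real
# channels (real, imaginary). Three modes:
#   zero         - R(x) = 0 (plain truncated Neumann series / Landweber);
#   image_only   - R(x) = CNN_I(x), the standard Neumann-network regularizer;
#   multi_domain - R(x) = CNN_I(x) + ifft2c(CNN_F(fft2c(x))), the parallel
#                  image-domain + frequency-domain block.
# For algebra tests the image/freq slots also accept plain functions
# (complex matrix -> complex matrix), applied verbatim in inference mode.

#' Construct a regularization block
#'
#' @param mode One of `"zero"`, `"image_only"`, `"multi_domain"`.
#' @param image,freq The image-domain / frequency-domain components: a
#'   [unet_init()] network with 2 input and 2 output channels, or a plain
#'   function `complex matrix -> complex matrix` (inference only; useful for
#'   closed-form checks).
#' @return Object of class `regularizer`.
#' @export
regularizer <- function(mode = c("zero", "image_only", "multi_domain"),
                        image = NULL, freq = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("image_only", "multi_domain") && is.null(image))
    stop("mode '", mode, "' needs an image-domain component")
  if (mode == "multi_domain" && is.null(freq))
    stop("mode 'multi_domain' needs a frequency-domain component")
  structure(list(mode = mode, image = image, freq = freq), class = "regularizer")
}

#' Build a CNN regularizer with fresh parameters
#'
#' @param mode Regularizer mode (see [regularizer()]).
#' @param spec A [unet_spec()] with 2 input/output channels; used for both
#'   domains (independent parameter sets).
#' @return A `regularizer`.
#' @export
make_cnn_regularizer <- function(mode = c("image_only", "multi_domain"),
                                 spec = unet_spec(in_ch = 2L, out_ch = 2L)) {
  mode <- match.arg(mode)
  regularizer(mode,
              image = unet_init(spec),
              freq = if (mode == "multi_domain") unet_init(spec) else NULL)
}

apply_component <- function(comp, x) {
  if (inherits(comp, "unet")) {
    ad_ch2c(unet_forward(comp, ad_c2ch(x)), drop_coil = TRUE)
  } else if (is.function(comp)) {
    if (ad_tracing()) stop("function-valued regularizer components are inference-only")
    comp(ad_val(x))
  } else stop("regularizer component must be a unet or a function")
}

#' Apply a regularization block to a complex image
#'
#' Deterministic given fixed parameters; shape preserving. `zero` mode
#' returns exact zeros.
#'
#' @param R A [regularizer()].
#' @param x Complex matrix (or tape node).
#' @return Complex matrix (or node) of the same shape.
#' @export
apply_regularizer <- function(R, x) {
  stopifnot(inherits(R, "regularizer"))
  if (R$mode == "zero") {
    v <- ad_val(x)
    return(array(0i, dim(v)))
  }
  out <- apply_component(R$image, x)
  if (R$mode == "multi_domain") {
    fr <- ad_ifft2c(apply_component(R$freq, ad_fft2c(x)))
    out <- ad_add(out, fr)
  }
  out
}
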