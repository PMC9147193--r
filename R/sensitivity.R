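# Coil sensitivity maps: application/combination operators, the non-learned
# ACS low-resolution estimator, and the CNN estimator that maps ACS
# zero-filled coil images to normalized maps.

#' Apply coil sensitivity maps to an image
#'
#' Coil expansion: coil `c` of the output is `S_c * x` pixelwise (the `S` of
#' the forward operator `A = M o F o S`).
#'
#' @param S Complex `(rows, cols, coils)` sensitivity maps.
#' @param x Complex (or real) matrix.
#' @return Complex `(rows, cols, coils)` multi-coil image.
#' @export
apply_maps <- function(S, x) {
  dS <- dim(ad_val(S)); dx <- dim(ad_val(x))
  if (length(dS) != 3L || any(dS[1:2] != dx[1:2])) stop("shape mismatch between maps and image")
  ad_apply_maps(S, x)
}

#' Combine a multi-coil image with conjugate sensitivity weights
#'
#' The adjoint of [apply_maps()]: `sum_c Conj(S_c) * img_c`. When the maps
#' are pixelwise normalized (`sum_c |S_c|^2 = 1`) this is the exact left
#' inverse of [apply_maps()], which is how the map "inverse" in the k-space
#' recursion is realized (S maps one image to many coils, so a literal
#' inverse does not exist).
#'
#' @param S Complex `(rows, cols, coils)` maps.
#' @param imgs Complex `(rows, cols, coils)` multi-coil image.
#' @return Complex matrix.
#' @export
reduce_maps <- function(S, imgs) {
  dS <- dim(ad_val(S)); di <- dim(ad_val(imgs))
  if (!identical(dS, di)) stop("shape mismatch between maps and multi-coil image")
  ad_reduce_maps(S, imgs)
}

#' Pixelwise RSS normalization of sensitivity maps
#'
#' Divides each coil by the pixelwise root sum of squares so that
#' `sum_c |S_c|^2 = 1` wherever the maps carry signal; pixels whose RSS is
#' below `threshold * max(RSS)` are zeroed (empty background guard).
#'
#' @param S Complex `(rows, cols, coils)` array.
#' @param threshold Relative RSS floor (default `1e-3`).
#' @return Normalized maps with attribute `normalized = TRUE`.
#' @export
normalize_maps <- function(S, threshold = 1e-3) {
  r <- rss_combine(S)
  keep <- r >= threshold * max(r)
  rsafe <- r
  rsafe[!keep] <- 1
  out <- S * as.vector(keep / rsafe)
  attr(out, "normalized") <- TRUE
  out
}

#' ACS low-resolution sensitivity estimate
#'
#' The non-learned estimator: keep only the fully sampled ACS columns of the
#' measured k-space (zeros elsewhere), inverse Fourier transform per coil,
#' and normalize pixelwise by the RSS. The result is a smooth low-resolution
#' estimate of the coil profiles (up to a common pixelwise phase), the
#' classical self-calibrated alternative to the learned estimator.
#' Invariant to positive rescaling of `y` (maps are ratios).
#'
#' By default the ACS block is apodized with a Hann window before the
#' inverse transform; the hard truncation otherwise leaves Gibbs ringing in
#' the coil images that leaks into the map ratios near object edges.
#' Apodization changes nothing for the RSS-normalized ratios of
#' coil-independent structure (all coils share the same blurred anatomy)
#' but substantially reduces edge error on realistic scenes.
#'
#' @param y Complex `(rows, cols, coils)` under-sampled k-space.
#' @param m The `sampling_mask` (its ACS block is used).
#' @param threshold Background floor for [normalize_maps()].
#' @param apodize Apply a Hann window across the ACS columns (default TRUE).
#' @return Normalized complex maps.
#' @export
acs_lowres_maps <- function(y, m, threshold = 1e-3, apodize = TRUE) {
  stopifnot(inherits(m, "sampling_mask"))
  if (m$acs_end < m$acs_start) stop("mask has an empty ACS block")
  imgs <- ifft2c(acs_apodized(y, m, apodize))
  normalize_maps(imgs, threshold)
}

# ACS-masked k-space, optionally Hann-windowed across the ACS columns.
acs_apodized <- function(y, m, apodize) {
  ya <- apply_mask(y, acs_mask(m))
  if (!apodize) return(ya)
  idx <- m$acs_start:m$acs_end
  w <- rep(0, m$num_cols)
  w[idx] <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / (length(idx) + 1))
  ya * as.vector(rep(w, each = dim(y)[1L]))
}

#' CNN sensitivity estimation
#'
#' The learned path `S = CNN_C(F^-1 M_ACS y)`: the ACS-masked zero-filled
#' coil images are channel-packed (2C real channels), refined by the
#' estimator network, unpacked to complex maps and normalized pixelwise by
#' their RSS (so the forward model stays well conditioned; the output always
#' satisfies `sum_c |S_c|^2 <= 1`). The network is applied residually
#' (`input + net(input)`), so with the default zero-initialized final layer
#' the estimate starts exactly at the classical ACS low-resolution maps and
#' the network learns a correction; a non-residual estimator would start at
#' zero maps, through which no reconstruction gradient can flow. With
#' `net = NULL` (identity estimator) this reduces exactly to
#' [acs_lowres_maps()]. Differentiable: inside a tape the network and
#' normalization are tracked, so the maps can be trained jointly with the
#' reconstruction loss.
#'
#' @param y Complex `(rows, cols, coils)` under-sampled k-space.
#' @param m The `sampling_mask`.
#' @param net A [unet_init()] network with `2 * coils` input and output
#'   channels, or `NULL` for the identity estimator.
#' @param per_coil If `TRUE`, apply a 2-channel network to each coil
#'   independently instead of jointly to all `2 * coils` channels.
#' @param threshold Background floor (support is taken from the zero-filled
#'   images, which are constants of the graph).
#' @param apodize Hann-window the ACS block of the network input, matching
#'   [acs_lowres_maps()].
#' @return Normalized complex maps (array or tape node).
#' @export
cnn_maps <- function(y, m, net = NULL, per_coil = FALSE, threshold = 1e-3,
                     apodize = TRUE) {
  stopifnot(inherits(m, "sampling_mask"))
  zf <- ifft2c(acs_apodized(ad_val(y), m, apodize))
  C <- dim(zf)[3L]
  if (is.null(net)) {
    out <- zf
  } else {
    stopifnot(inherits(net, "unet"))
    if (per_coil) {
      if (net$spec$in_ch != 2L) stop("per-coil estimator needs a 2-channel network")
      packed <- lapply(seq_len(C), function(cc) {
        tc <- pack_channels(zf[, , cc, drop = FALSE])
        ad_add(unet_forward(net, tc), tc)
      })
      t <- packed[[1L]]
      if (C > 1L) for (cc in 2:C) t <- ad_concat(t, packed[[cc]])
      # packed order here is (re1, im1, re2, im2, ...); reorder to all-re, all-im
      idx <- c(seq(1L, 2L * C, by = 2L), seq(2L, 2L * C, by = 2L))
      t <- ad_reorder_ch(t, idx)
      out <- ad_ch2c(t)
    } else {
      if (net$spec$in_ch != 2L * C)
        stop(sprintf("estimator expects %d channels but data has %d coils", net$spec$in_ch, C))
      tz <- pack_channels(zf)
      out <- ad_ch2c(ad_add(unet_forward(net, tz), tz))
    }
  }
  r0 <- rss_combine(ad_val(out))
  support <- (r0 >= threshold * max(r0)) * 1
  res <- ad_norm_maps(out, support)
  if (!ad_tracing()) attr(res, "normalized") <- TRUE
  res
}

# Channel permutation (constant index).
ad_reorder_ch <- function(t, idx) {
  tv <- ad_val(t)
  inv <- order(idx)
  ad_op(tv[, , idx, drop = FALSE], list(t),
        function(g) list(g[, , inv, drop = FALSE]))
}
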