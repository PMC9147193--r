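# Minimal reverse-mode differentiation engine.
#
# Values flow through small op wrappers (ad_*). Outside a tape the wrappers
# are pass-through numerics with no bookkeeping, so the reconstruction
# recursions run identically in inference and training. Inside a tape
# (with_tape) each op records its parents and a vector-Jacobian closure;
# ad_backward replays the tape in reverse, accumulating gradients into
# trainable leaves (nn_param environments).
#
# Complex convention: a complex tensor is its real and imaginary parts; the
# stored gradient of a complex value z is the complex array
# g = dL/dRe(z) + 1i * dL/dIm(z). Under this convention the backward of a
# complex-linear operator is its adjoint (conjugate transpose), e.g. the
# backward of the unitary fft2c is ifft2c.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tracing <- function() !is.null(.ad$tape)

is_adnode <- function(x) is.environment(x)

#' @keywords internal
ad_val <- function(x) if (is.environment(x)) x$value else x

#' Trainable parameter leaf
#'
#' Wraps an array as a leaf of the differentiation graph. Gradients
#' accumulate into `$grad`; the Adam optimizer keeps its moment state on the
#' same environment.
#'
#' @param value Numeric array (or scalar).
#' @return An environment of class `nn_param`.
#' @export
nn_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "nn_param"
  e
}

ad_node <- function(value, parents, vjp) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$vjp <- vjp
  nd$grad <- NULL
  class(nd) <- "ad_node"
  tp <- .ad$tape
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

# Record an op: `value` computed from ad_val()s, `parents` the input objects
# (environments participate in backward, raw arrays are constants), `vjp` a
# function(grad) returning a list of parent gradients (NULL for constants).
ad_op <- function(value, parents, vjp) {
  if (!ad_tracing()) return(value)
  has_env <- FALSE
  for (p in parents) if (is.environment(p)) { has_env <- TRUE; break }
  if (!has_env) return(value)
  ad_node(value, parents, vjp)
}

#' Run a closure under a fresh gradient tape
#'
#' @param fn Zero-argument function building the forward computation.
#' @return List with `out` (the function's value, usually the loss node) and
#'   `tape` (for [ad_backward()]).
#' @export
with_tape <- function(fn) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  old <- .ad$tape
  .ad$tape <- tp
  on.exit(.ad$tape <- old)
  out <- fn()
  list(out = out, tape = tp)
}

#' Reverse pass over a tape
#'
#' Seeds the root gradient and accumulates vector-Jacobian products into
#' every `nn_param` reachable from it.
#'
#' @param tape Tape from [with_tape()].
#' @param root The output node (must be on the tape).
#' @param seed Gradient seed (1 for a scalar loss).
#' @export
ad_backward <- function(tape, root, seed = 1) {
  if (!is.environment(root)) stop("root is not a recorded node (nothing to differentiate)")
  root$grad <- seed
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (is.environment(p) && !is.null(gs[[k]])) {
        p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
      }
    }
    nd$grad <- NULL   # release memory as we go
  }
  invisible(NULL)
}

#' Collect trainable leaves from a nested structure
#' @param x Nested list of `nn_param`s (and other objects, ignored).
#' @return Flat list of `nn_param` environments.
#' @export
collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (inherits(e, "nn_param")) out[[length(out) + 1L]] <<- e
    else if (is.list(e)) for (el in e) walk(el)
  }
  walk(x)
  out
}

#' Zero stored gradients on a parameter list
#' @param params List of `nn_param`s.
#' @export
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- generic elementwise ops (real or complex where noted) ----

ad_add <- function(a, b) {
  ad_op(ad_val(a) + ad_val(b), list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_op(ad_val(a) - ad_val(b), list(a, b), function(g) list(g, -g))
}

# Elementwise product of two real tensors (either may be a node).
ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# Elementwise quotient of real tensors.
ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  val <- av / bv
  ad_op(val, list(a, b), function(g) list(g / bv, -g * val / bv))
}

# Multiply by a plain numeric constant.
ad_const_mul <- function(a, k) {
  ad_op(ad_val(a) * k, list(a), function(g) list(g * k))
}

# Mean of all entries (real).
ad_mean <- function(a) {
  av <- ad_val(a)
  n <- length(av)
  ad_op(mean(av), list(a), function(g) list(array(g / n, dim(av) %||% n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scale a (real or complex) tensor by a real scalar, possibly trainable.
ad_scale <- function(z, lam) {
  zv <- ad_val(z); lv <- ad_val(lam)
  ad_op(zv * lv, list(z, lam), function(g) {
    glam <- if (is.complex(zv) || is.complex(g)) sum(Re(Conj(g) * zv)) else sum(g * zv)
    list(g * lv, glam)
  })
}

# ---- complex-linear ops: backward = adjoint ----

ad_fft2c <- function(z) {
  ad_op(fft2c(ad_val(z)), list(z), function(g) list(ifft2c(g)))
}

ad_ifft2c <- function(z) {
  ad_op(ifft2c(ad_val(z)), list(z), function(g) list(fft2c(g)))
}

ad_apply_mask <- function(z, m) {
  ad_op(apply_mask(ad_val(z), m), list(z), function(g) list(apply_mask(g, m)))
}

# y_c = S_c * x  (coil expansion); S and/or x may be nodes.
ad_apply_maps <- function(S, x) {
  Sv <- ad_val(S); xv <- ad_val(x)
  ad_op(Sv * as.vector(xv), list(S, x), function(g) {
    gS <- g * as.vector(Conj(xv))
    gx <- rowSums(Conj(Sv) * g, dims = 2L)
    list(gS, gx)
  })
}

# x = sum_c Conj(S_c) * z_c  (conjugate-weighted coil combine).
ad_reduce_maps <- function(S, z) {
  Sv <- ad_val(S); zv <- ad_val(z)
  ad_op(rowSums(Conj(Sv) * zv, dims = 2L), list(S, z), function(g) {
    gS <- as.vector(Conj(g)) * zv      # anti-linear in S
    gz <- Sv * as.vector(g)
    list(gS, gz)
  })
}

# ---- real nonlinear reductions of complex tensors ----

# Root sum of squares over the coil axis; also |z| for a single image when
# z is (rows, cols, 1). Gradient g * z / rss with 0/0 guarded to 0.
ad_rss <- function(z) {
  zv <- ad_val(z)
  val <- rss_combine(zv)
  ad_op(val, list(z), function(g) {
    denom <- val
    denom[denom == 0] <- 1
    list(zv * as.vector(g / denom))
  })
}

# Complex magnitude of a 2-D image.
ad_cmod <- function(z) {
  zv <- ad_val(z)
  val <- Mod(zv)
  ad_op(val, list(z), function(g) {
    denom <- val
    denom[denom == 0] <- 1
    list(zv * (g / denom))
  })
}

# ---- complex <-> packed-channel bridges ----

ad_c2ch <- function(z) {
  zv <- ad_val(z)
  if (is.matrix(zv)) { zm <- zv; dim(zm) <- c(dim(zv), 1L) } else zm <- zv
  was_mat <- is.matrix(zv)
  ad_op(pack_channels(zm), list(z), function(g) {
    gz <- unpack_channels(g)
    if (was_mat) dim(gz) <- dim(gz)[1:2]
    list(gz)
  })
}

ad_ch2c <- function(t, drop_coil = FALSE) {
  tv <- ad_val(t)
  val <- unpack_channels(tv)
  if (drop_coil && dim(val)[3L] == 1L) dim(val) <- dim(val)[1:2]
  ad_op(val, list(t), function(g) {
    gm <- g
    if (is.matrix(gm)) dim(gm) <- c(dim(gm), 1L)
    list(pack_channels(gm))
  })
}

# Pixelwise RSS-normalization of estimated coil maps with a constant support
# mask (1 where kept, 0 where the background is zeroed).
ad_norm_maps <- function(z, support) {
  zv <- ad_val(z)
  r <- rss_combine(zv)
  rsafe <- r
  rsafe[rsafe == 0] <- 1
  val <- zv * as.vector(support / rsafe)
  ad_op(val, list(z), function(g) {
    gm <- g * as.vector(support)
    direct <- gm * as.vector(1 / rsafe)
    dLdr <- -rowSums(Re(Conj(gm) * zv), dims = 2L) / rsafe^2
    via_r <- zv * as.vector(dLdr / rsafe)
    list(direct + via_r)
  })
}
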