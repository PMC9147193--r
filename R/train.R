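# Model constructors (U-Net baseline, image-domain Neumann network,
# multi-domain k-space network with learned sensitivity maps), the SSIM-loss
# training loop on the built-in autodiff engine, and checkpointing.

#' Training configuration
#'
#' @param lr Learning rate of the adaptive-moment (Adam) optimizer
#'   (study value `1e-4`).
#' @param epochs Number of passes over the training set (study value 50;
#'   the toy CPU profile used throughout the test suite is 5).
#' @param seed Integer seed governing initialization and data order.
#' @param batch_size Samples per update (default 1; gradients are not
#'   batched beyond this).
#' @param window SSIM-loss window.
#' @param verbose Print per-epoch losses.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 5L, seed = 0L, batch_size = 1L,
                         window = 7L, verbose = FALSE) {
  if (lr <= 0) stop("learning rate must be positive")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs), seed = as.integer(seed),
                 batch_size = as.integer(batch_size), window = as.integer(window),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Construct reconstruction models
#'
#' `mdnnsm_model()` builds the full multi-domain network: a sensitivity
#' estimator U-Net (`2*num_coils` channels), `num_blocks` regularization
#' blocks each with an image-domain and a frequency-domain U-Net (independent
#' parameters unless `share_params`), and trainable per-block step sizes
#' initialized to 1, accumulated in k-space. `neumann_model()` is the
#' standard image-domain Neumann network (image-only regularizers, fixed
#' ACS low-resolution sensitivity maps). `unet_model()` is the image-domain
#' U-Net baseline acting on the zero-filled magnitude image (residual
#' connection, so it equals the zero-filled baseline at initialization).
#'
#' @param num_coils Coil count of the data the model is built for.
#' @param num_blocks Iteration blocks `N` (default 6).
#' @param reg_spec [unet_spec()] for the regularizer networks (2 channels).
#' @param sens_spec [unet_spec()] for the sensitivity estimator.
#' @param share_params Share one regularization block across iterations.
#' @param lambda_init Initial step size for all blocks (default 1).
#' @param lambda_on_reg See [neumann_config()].
#' @param seed Seed for parameter initialization.
#' @return Object of class `recon_model`.
#' @export
mdnnsm_model <- function(num_coils, num_blocks = 6L,
                         reg_spec = unet_spec(in_ch = 2L, out_ch = 2L, depth = 2L, width = 4L),
                         sens_spec = unet_spec(in_ch = 2L * num_coils, out_ch = 2L * num_coils,
                                               depth = 2L, width = 4L),
                         share_params = FALSE, lambda_init = 1,
                         lambda_on_reg = TRUE, seed = 0L) {
  with_seed(seed, {
    sens_net <- unet_init(sens_spec)
    regs <- if (share_params) make_cnn_regularizer("multi_domain", reg_spec)
            else lapply(seq_len(num_blocks), function(j) make_cnn_regularizer("multi_domain", reg_spec))
    lambdas <- lapply(seq_len(num_blocks + 1L), function(j) nn_param(lambda_init))
    structure(list(kind = "mdnnsm", num_coils = as.integer(num_coils),
                   num_blocks = as.integer(num_blocks),
                   sens_net = sens_net, regs = regs, lambdas = lambdas,
                   share_params = isTRUE(share_params),
                   lambda_on_reg = isTRUE(lambda_on_reg), seed = as.integer(seed)),
              class = "recon_model")
  })
}

#' @rdname mdnnsm_model
#' @param use_maps How the image-domain Neumann network treats coils:
#'   `"none"` (default) reconstructs the multi-coil image stack without
#'   sensitivity maps, regularizing all coils jointly as channels and
#'   combining with root sum of squares at the end — the original
#'   comparator network; `"acs"` uses fixed ACS low-resolution maps in the
#'   forward model (a SENSE-style variant).
#' @export
neumann_model <- function(num_coils, num_blocks = 6L,
                          use_maps = c("none", "acs"),
                          reg_spec = NULL,
                          share_params = FALSE, lambda_init = 1,
                          lambda_on_reg = TRUE, seed = 0L) {
  use_maps <- match.arg(use_maps)
  if (is.null(reg_spec)) {
    ch <- if (use_maps == "none") 2L * as.integer(num_coils) else 2L
    reg_spec <- unet_spec(in_ch = ch, out_ch = ch, depth = 2L, width = 4L)
  }
  with_seed(seed, {
    regs <- if (share_params) make_cnn_regularizer("image_only", reg_spec)
            else lapply(seq_len(num_blocks), function(j) make_cnn_regularizer("image_only", reg_spec))
    lambdas <- lapply(seq_len(num_blocks + 1L), function(j) nn_param(lambda_init))
    structure(list(kind = "neumann", num_coils = as.integer(num_coils),
                   num_blocks = as.integer(num_blocks), use_maps = use_maps,
                   sens_net = NULL, regs = regs, lambdas = lambdas,
                   share_params = isTRUE(share_params),
                   lambda_on_reg = isTRUE(lambda_on_reg), seed = as.integer(seed)),
              class = "recon_model")
  })
}

#' @rdname mdnnsm_model
#' @param net_spec [unet_spec()] for the plain U-Net baseline (1 channel).
#' @export
unet_model <- function(num_coils,
                       net_spec = unet_spec(in_ch = 1L, out_ch = 1L, depth = 2L, width = 8L),
                       seed = 0L) {
  with_seed(seed, {
    structure(list(kind = "unet", num_coils = as.integer(num_coils),
                   net = unet_init(net_spec), seed = as.integer(seed)),
              class = "recon_model")
  })
}

model_params <- function(model) {
  switch(model$kind,
         mdnnsm = collect_params(list(model$sens_net, model$regs, model$lambdas)),
         neumann = collect_params(list(model$regs, model$lambdas)),
         unet = collect_params(model$net),
         stop("unknown model kind"))
}

model_config <- function(model) {
  if (model$kind == "unet") return(NULL)
  neumann_config(
    num_blocks = model$num_blocks,
    lambdas = model$lambdas,
    regularizers = model$regs,
    accumulate_domain = if (model$kind == "mdnnsm") "kspace" else "image",
    lambda_on_reg = model$lambda_on_reg)
}

#' Reconstruct with a model (inference)
#'
#' Dispatches on the model kind: MDNNSM estimates maps with its sensitivity
#' network and runs the k-space recursion; the Neumann model uses ACS
#' low-resolution maps and the image-domain recursion (returning the
#' magnitude); the U-Net baseline refines the zero-filled image.
#'
#' @param model A `recon_model`.
#' @param y Complex `(rows, cols, coils)` under-sampled k-space.
#' @param mask The `sampling_mask` used for `y`.
#' @return Nonnegative real image matrix.
#' @export
model_reconstruct <- function(model, y, mask) {
  stopifnot(inherits(model, "recon_model"))
  out <- model_forward(model, y, mask)
  ad_val(out)
}

# Forward pass shared by inference and training (tape-aware).
model_forward <- function(model, y, mask) {
  if (model$kind == "unet") {
    zf <- zero_filled(y)
    t0 <- array(zf, c(dim(zf), 1L))
    res <- unet_forward(model$net, t0)
    sq <- ad_op(ad_val(res)[, , 1L], list(res),
                function(g) list(array(g, c(dim(g), 1L))))
    return(ad_add(sq, zf))
  }
  cfg <- model_config(model)
  if (model$kind == "mdnnsm") {
    S <- cnn_maps(y, mask, model$sens_net)
    A <- forward_model(mask, S)
    mdnnsm_reconstruct(y, A, cfg)
  } else if (identical(model$use_maps, "acs")) {
    S <- acs_lowres_maps(y, mask)
    A <- forward_model(mask, S)
    ad_cmod(neumann_reconstruct(y, A, cfg))
  } else {
    # map-free comparator: per-coil recursion, RSS combine of the stack
    A <- forward_model(mask, NULL)
    out <- neumann_reconstruct(y, A, cfg)
    if (length(dim(ad_val(out))) == 3L) ad_rss(out) else ad_cmod(out)
  }
}

snapshot_params <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$value <- values[[i]]
  invisible(NULL)
}

#' Train a reconstruction model
#'
#' Stochastic training with the SSIM loss (`1 - SSIM`) between the target
#' magnitude image and the model output, using Adam. Deterministic given the
#' seed (single-threaded execution): two runs with identical configuration
#' produce bit-identical checkpoints. Aborts with diagnostics if the loss
#' becomes non-finite. When validation data is supplied, the returned
#' checkpoint holds the parameters of the epoch with the lowest mean
#' validation NMSE; otherwise the final parameters.
#'
#' @param model A `recon_model` (modified in place; also returned inside the
#'   checkpoint).
#' @param data List of training samples, each a list with `y`, `mask`,
#'   `target` (as produced by [simulate_dataset()]).
#' @param cfg A [train_config()].
#' @param val_data Optional list of validation samples of the same form.
#' @return Object of class `recon_checkpoint`: list with `model`, `history`
#'   (data frame of epoch, mean train loss, mean validation NMSE), `cfg`,
#'   and `best_epoch`.
#' @export
train <- function(model, data, cfg = train_config(), val_data = NULL) {
  stopifnot(inherits(model, "recon_model"), length(data) >= 1L)
  params <- model_params(model)
  set.seed(cfg$seed)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_nmse = numeric())
  best <- list(nmse = Inf, values = NULL, epoch = NA_integer_)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(data))
    losses <- numeric(length(ord))
    for (ii in seq_along(ord)) {
      s <- data[[ord[ii]]]
      tr <- with_tape(function() {
        pred <- model_forward(model, s$y, s$mask)
        ssim_loss(pred, s$target, window = cfg$window)
      })
      lv <- ad_val(tr$out)
      if (!is.finite(lv))
        stop(sprintf("training diverged: non-finite loss at epoch %d, step %d", ep, ii))
      ad_backward(tr$tape, tr$out)
      step <- step + 1L
      adam_step(params, cfg$lr, step)
      losses[ii] <- lv
    }
    vn <- NA_real_
    if (!is.null(val_data)) {
      vn <- mean(vapply(val_data, function(s)
        nmse(model_reconstruct(model, s$y, s$mask), s$target), numeric(1L)))
      if (vn < best$nmse)
        best <- list(nmse = vn, values = snapshot_params(params), epoch = ep)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                         val_nmse = vn))
    if (cfg$verbose)
      message(sprintf("epoch %d: train loss %.5f, val NMSE %s", ep, mean(losses),
                      ifelse(is.na(vn), "-", sprintf("%.5f", vn))))
  }
  if (!is.null(best$values)) restore_params(params, best$values)
  structure(list(model = model, history = history, cfg = cfg,
                 best_epoch = best$epoch),
            class = "recon_checkpoint")
}

#' Save / load a training checkpoint
#'
#' The checkpoint is written as an RDS archive of plain arrays (a flat
#' key-value map of every parameter) next to a human-readable JSON sidecar
#' recording the model kind and configuration.
#'
#' @param ckpt A `recon_checkpoint` (or `recon_model`).
#' @param path Output `.rds` path; the sidecar is `<path>.json`.
#' @return `save_checkpoint()`: the path, invisibly. `load_checkpoint()`:
#'   the restored `recon_checkpoint`.
#' @export
save_checkpoint <- function(ckpt, path) {
  if (inherits(ckpt, "recon_model")) ckpt <- structure(list(model = ckpt), class = "recon_checkpoint")
  model <- ckpt$model
  values <- snapshot_params(model_params(model))
  saveRDS(list(model = model, values = values, history = ckpt$history,
               cfg = ckpt$cfg, best_epoch = ckpt$best_epoch), path)
  spec_of <- function(net) if (!is.null(net)) unclass(net$spec)
  reg1 <- if (!is.null(model$regs)) {
    r <- if (inherits(model$regs, "regularizer")) model$regs else model$regs[[1L]]
    list(mode = r$mode, unet = spec_of(r$image))
  }
  meta <- list(kind = model$kind, num_coils = model$num_coils,
               num_blocks = if (!is.null(model$num_blocks)) model$num_blocks,
               share_params = model$share_params,
               lambda_on_reg = model$lambda_on_reg,
               regularizer = reg1,
               sens_unet = if (!is.null(model$sens_net)) spec_of(model$sens_net),
               unet = if (!is.null(model$net)) spec_of(model$net),
               train = if (!is.null(ckpt$cfg)) unclass(ckpt$cfg),
               n_params = length(values),
               best_epoch = ckpt$best_epoch)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  blob <- readRDS(path)
  model <- blob$model
  restore_params(model_params(model), blob$values)
  structure(list(model = model, history = blob$history, cfg = blob$cfg,
                 best_epoch = blob$best_epoch),
            class = "recon_checkpoint")
}
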