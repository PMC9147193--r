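test_that("single-sample overfit: loss decreases within the first steps", {
  ds <- simulate_dataset(1, 32, 32, 2, 2, 0.25, noise_sigma = 0, seed = 40)
  model <- mdnnsm_model(2, num_blocks = 2,
                        reg_spec = unet_spec(2, 2, depth = 1, width = 3),
                        sens_spec = unet_spec(4, 4, depth = 1, width = 3),
                        seed = 1)
  params <- neumannmri:::model_params(model)
  s <- ds[[1]]
  losses <- numeric(12)
  for (i in seq_along(losses)) {
    tr <- with_tape(function()
      ssim_loss(neumannmri:::model_forward(model, s$y, s$mask), s$target))
    losses[i] <- ad_val(tr$out)
    ad_backward(tr$tape, tr$out)
    adam_step(params, 1e-3, i)
  }
  expect_lt(min(losses[-1]), losses[1])
  # SSIM on the overfit sample is no worse than at initialization
  expect_lte(losses[length(losses)], losses[1] + 1e-8)
})

test_that("training is deterministic: identical seeds give bit-identical checkpoints", {
  ds <- simulate_dataset(2, 32, 32, 2, 2, 0.25, seed = 41)
  run <- function() {
    model <- neumann_model(2, num_blocks = 1,
                           reg_spec = unet_spec(4, 4, depth = 1, width = 3),
                           seed = 7)
    train(model, ds, train_config(lr = 1e-3, epochs = 2, seed = 7))
  }
  c1 <- run()
  c2 <- run()
  v1 <- neumannmri:::snapshot_params(neumannmri:::model_params(c1$model))
  v2 <- neumannmri:::snapshot_params(neumannmri:::model_params(c2$model))
  expect_identical(v1, v2)
  expect_identical(c1$history, c2$history)
})

test_that("training tracks validation and restores the best parameters", {
  ds <- simulate_dataset(2, 32, 32, 2, 2, 0.25, seed = 42)
  val <- simulate_dataset(1, 32, 32, 2, 2, 0.25, seed = 43)
  model <- neumann_model(2, num_blocks = 1,
                         reg_spec = unet_spec(4, 4, depth = 1, width = 3), seed = 3)
  ck <- train(model, ds, train_config(lr = 1e-3, epochs = 3, seed = 3), val)
  expect_equal(nrow(ck$history), 3)
  expect_true(all(is.finite(ck$history$val_nmse)))
  expect_equal(ck$best_epoch, which.min(ck$history$val_nmse))
  # restored parameters reproduce the best epoch's validation NMSE
  vn <- mean(sapply(val, function(s)
    nmse(model_reconstruct(ck$model, s$y, s$mask), s$target)))
  expect_equal(vn, min(ck$history$val_nmse), tolerance = 1e-12)
})

test_that("checkpoints round-trip through disk", {
  ds <- simulate_dataset(1, 32, 32, 2, 2, 0.25, seed = 44)
  model <- neumann_model(2, num_blocks = 1,
                         reg_spec = unet_spec(4, 4, depth = 1, width = 3), seed = 5)
  ck <- train(model, ds, train_config(lr = 1e-3, epochs = 1, seed = 5))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  ck2 <- load_checkpoint(path)
  s <- ds[[1]]
  expect_identical(model_reconstruct(ck$model, s$y, s$mask),
                   model_reconstruct(ck2$model, s$y, s$mask))
})

test_that("training aborts with diagnostics on divergence", {
  ds <- simulate_dataset(1, 32, 32, 2, 2, 0.25, seed = 45)
  model <- neumann_model(2, num_blocks = 1,
                         reg_spec = unet_spec(4, 4, depth = 1, width = 3), seed = 6)
  params <- neumannmri:::model_params(model)
  params[[1]]$value[1] <- NaN
  expect_error(train(model, ds, train_config(epochs = 1)), "non-finite")
})

test_that("training configuration is validated", {
  expect_error(train_config(lr = 0), "positive")
  expect_error(train_config(epochs = 0), "epochs")
})
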