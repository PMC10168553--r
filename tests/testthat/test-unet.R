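test_that("network shapes, ranges and determinism hold", {
  cfg <- unet_config(input_size = 64L, depth = 3L, base_channels = 4L,
                     batch_size = 2L, max_epochs = 1L,
                     early_stop_patience = 1L, seed = 2)
  model <- build_unet(cfg)
  set.seed(1)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  p <- lungcontour:::unet_forward(model, x)$p
  expect_identical(dim(p), c(64L, 64L, 1L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(p)))
  # inference determinism and identical weights from the same seed
  expect_identical(p, lungcontour:::unet_forward(model, x)$p)
  expect_identical(model$layers, build_unet(cfg)$layers)
  # indivisible input size rejected
  expect_error(unet_config(input_size = 60L, depth = 3L), "divisible")
  ph <- generate_phantom(phantom_spec(seed = 4))
  pm <- predict_unet(model, ph$image)
  expect_s3_class(pm, "ProbabilityMap")
  expect_identical(dim(pm$pixels), dim(ph$image$pixels))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- unet_config(input_size = 16L, depth = 2L, base_channels = 3L,
                     batch_size = 2L, max_epochs = 1L,
                     early_stop_patience = 1L, seed = 3)
  model <- build_unet(cfg)
  set.seed(42)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  fw <- lungcontour:::unet_forward(model, x, keep_cache = TRUE)
  g <- lungcontour:::unet_backward(model, fw$cache, fw$p, y)
  loss_at <- function(m) lungcontour:::bce_loss(
    lungcontour:::unet_forward(m, x)$p, y)
  eps <- 1e-4
  set.seed(7)
  for (nm in c("enc1_conv1", "bott_conv2", "dec1_up", "out")) {
    i <- sample(length(model$layers[[nm]]$W), 1)
    m2 <- model; m2$layers[[nm]]$W[i] <- m2$layers[[nm]]$W[i] + eps
    m3 <- model; m3$layers[[nm]]$W[i] <- m3$layers[[nm]]$W[i] - eps
    num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
    ana <- g[[nm]]$dW[i]
    # single-precision forward passes bound the attainable agreement
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 0.08)
  }
})

test_that("training bookkeeping follows the early-stopping contract", {
  recs <- make_labelled_cohort(6, seed = 21)
  ds <- records_to_dataset(recs)
  cfg0 <- unet_config(input_size = 64L, depth = 3L, base_channels = 4L,
                      batch_size = 4L, max_epochs = 0L,
                      early_stop_patience = 0L, seed = 5)
  model <- build_unet(cfg0)
  fit0 <- train_unet(model, ds, cfg0)
  expect_identical(fit0$model$layers, model$layers)  # untouched
  expect_identical(nrow(fit0$history), 0L)
  # patience 1 with a frozen optimiser (lr = 0): stops after 2 epochs
  cfg1 <- unet_config(input_size = 64L, depth = 3L, base_channels = 4L,
                      batch_size = 4L, max_epochs = 10L,
                      early_stop_patience = 1L, learning_rate = 0,
                      seed = 5)
  fit1 <- train_unet(build_unet(cfg1), ds, cfg1)
  expect_lte(nrow(fit1$history), 2L)
  expect_error(train_unet(model, list(x = array(0, c(64, 64, 1, 0)),
                                      y = array(0, c(64, 64, 1, 0))), cfg0),
               "empty dataset")
})

test_that("a small phantom set is overfit to high pixel accuracy", {
  recs <- make_labelled_cohort(8, seed = 77)
  ds <- records_to_dataset(recs)
  cfg <- unet_config(input_size = 64L, depth = 3L, base_channels = 8L,
                     batch_size = 4L, max_epochs = 60L,
                     early_stop_patience = 60L, seed = 9)
  fit <- train_unet(build_unet(cfg), ds, cfg)
  expect_gt(max(fit$history$train_acc), 0.99)
  # training loss improves substantially from start to best epoch
  expect_lt(min(fit$history$train_loss), 0.2 * fit$history$train_loss[1])
  # the best-checkpoint validation sequence is non-increasing by construction
  expect_true(all(diff(cummin(fit$history$val_loss)) <= 0))
})
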