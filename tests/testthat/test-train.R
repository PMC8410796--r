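# Scenario training loop: CLR schedule, checkpointing, determinism.

make_toy_features <- function(n_pos = 30, n_neg = 120, d = 8, sep = 2,
                              seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), c(n_pos, n_neg))
    x <- matrix(rnorm((n_pos + n_neg) * d), ncol = d)
    x[y == 1, 1:2] <- x[y == 1, 1:2] + sep
    list(x = x, y = y)
  })
}

test_that("the cyclical learning rate hits its closed-form landmarks", {
  cfg <- clr_config(base_lr = 1e-7, max_lr = 1e-4, step_size_epochs = 4)
  ipe <- 25
  s <- 4 * ipe
  expect_equal(clr_at(0, ipe, cfg), 1e-7)
  expect_equal(clr_at(s, ipe, cfg), 1e-4)
  expect_equal(clr_at(3 * s, ipe, cfg), 1e-7 + (1e-4 - 1e-7) / 2)
  # envelope over 10 cycles: never below base, never above the halving ceiling
  it <- 0:(10 * 2 * s)
  lr <- clr_at(it, ipe, cfg)
  cycle <- floor(1 + it / (2 * s))
  ceiling_lr <- 1e-7 + (1e-4 - 1e-7) / 2^(cycle - 1)
  expect_true(all(lr >= 1e-7 - 1e-18))
  expect_true(all(lr <= ceiling_lr + 1e-18))
})

test_that("scenario configurations enforce the loss-sampler pairing", {
  expect_equal(scenario_config("ORI")$loss, "mse")
  expect_equal(scenario_config("ORI")$sampler, "naive")
  expect_equal(scenario_config("BON")$sampler, "fixed_ratio")
  expect_equal(scenario_config("BLF")$loss, "clf")
  expect_error(scenario_config("ORI", loss = "clf"),
               class = "melbalance_invalid_input")
  expect_error(scenario_config("BLF", loss = "mse"),
               class = "melbalance_invalid_input")
  expect_error(scenario_config("BON", sampler = "naive"),
               class = "melbalance_invalid_input")
  # baseline loss is switchable where allowed
  expect_equal(scenario_config("BON", loss = "bce")$loss, "bce")
})

test_that("training returns a full history and a min-val-loss checkpoint", {
  d <- make_toy_features()
  v <- make_toy_features(10, 40, seed = 2)
  sc <- scenario_config("BLF", epochs = 4, batch_size = 16, seed = 3)
  fit <- train_classifier(d$x, d$y, v$x, v$y, sc,
                          head = head_config(c(16, 8)),
                          clr = clr_config(base_lr = 1e-4, max_lr = 1e-2,
                                           step_size_epochs = 2))
  expect_s3_class(fit, "imbalance_fit")
  expect_equal(nrow(fit$history), 4L)
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss", "train_sen",
                    "train_spe", "val_sen", "val_spe") %in%
                    names(fit$history)))
  expect_equal(fit$checkpoint_epoch, which.min(fit$history$val_loss))
  # checkpoint optimality: re-scoring the checkpoint reproduces the minimum
  val_scores <- head_predict(fit$head, v$x)
  expect_equal(loss_clf(val_scores, v$y, missing_class = "zero"),
               min(fit$history$val_loss), tolerance = 1e-12)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("training is deterministic given the scenario seed", {
  d <- make_toy_features()
  v <- make_toy_features(10, 40, seed = 2)
  run <- function(seed) {
    sc <- scenario_config("BON", epochs = 3, batch_size = 16, seed = seed)
    train_classifier(d$x, d$y, v$x, v$y, sc, head = head_config(c(8, 4)),
                     clr = clr_config(base_lr = 1e-4, max_lr = 1e-2))
  }
  f1 <- run(7); f2 <- run(7); f3 <- run(8)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$history$val_loss, f3$history$val_loss)))
})

test_that("scenarios share initial weights and differ only via sampler and loss", {
  d <- make_toy_features()
  v <- make_toy_features(10, 40, seed = 2)
  fits <- lapply(c("ORI", "BON", "BLF"), function(nm) {
    sc <- scenario_config(nm, epochs = 2, batch_size = 16, seed = 11)
    train_classifier(d$x, d$y, v$x, v$y, sc, head = head_config(c(8, 4)),
                     clr = NULL, init_seed = 11)
  })
  h0 <- lapply(c("ORI", "BON", "BLF"), function(nm)
    build_head(head_config(c(8, 4)), ncol(d$x), seed = 11))
  expect_identical(h0[[1]]$params, h0[[2]]$params)
  expect_identical(h0[[1]]$params, h0[[3]]$params)
  # after training the scenarios have genuinely diverged
  expect_false(isTRUE(all.equal(fits[[1]]$history$train_loss,
                                fits[[3]]$history$train_loss)))
})

test_that("degenerate inputs are rejected", {
  d <- make_toy_features()
  sc <- scenario_config("BLF", epochs = 1, batch_size = 16, seed = 1)
  expect_error(train_classifier(d$x, d$y, matrix(0, 0, 8), numeric(0), sc),
               class = "melbalance_invalid_input")
  expect_error(train_classifier(list(), list(), d$x, d$y, sc),
               class = "melbalance_invalid_input")
})

test_that("training from images with on-draw augmentation runs end to end", {
  imgs <- lapply(1:24, function(i) {
    img <- toy_image(48, 64)
    img * (0.6 + 0.02 * i / 24) # slight brightness spread
  })
  y <- rep(c(1, 0), c(8, 16))
  # positives get a darker disc so the classes are actually separable
  for (i in which(y == 1)) imgs[[i]][20:28, 28:36, ] <- imgs[[i]][20:28, 28:36, ] * 0.4
  bb <- build_tiny_backbone(seed = 2)
  sc <- scenario_config("BLF", epochs = 2, batch_size = 8, seed = 5)
  fit <- train_classifier(imgs, y, imgs, y, sc,
                          head = head_config(c(8, 4)),
                          clr = NULL, backbone = bb,
                          augment = augment_config())
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$val_loss)))
  s <- predict(fit, backbone_features(bb, imgs))
  expect_length(s, 24L)
  expect_true(all(s > 0 & s < 1))
})

test_that("tidy and glance summarise a fit", {
  d <- make_toy_features()
  v <- make_toy_features(10, 40, seed = 2)
  sc <- scenario_config("ORI", epochs = 2, batch_size = 16, seed = 1)
  fit <- train_classifier(d$x, d$y, v$x, v$y, sc, head = head_config(c(8, 4)))
  td <- tidy(fit)
  expect_equal(nrow(td), 2L)
  expect_equal(td$scenario, c("ORI", "ORI"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$checkpoint_epoch, fit$checkpoint_epoch)
})
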