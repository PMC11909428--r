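# Training fixtures: a scale-8 phantom (62 x 96 x 15 voxels) keeps these fast.
seg_fixture <- function(n_bscans = 10, severity = 5, seed = 3) {
  ph <- small_phantom(severity = severity, seed = seed)
  g <- ph$profile$grid
  g10 <- grid_spec(g$n_rows, g$n_cols, n_bscans, g$dz, g$dx, g$dy)
  sub <- function(a) a[, , seq_len(n_bscans), drop = FALSE]
  list(volume = oct_volume(sub(ph$volume$intensities), g10),
       labels = oct_labels(sub(ph$labels$ilm_band), sub(ph$labels$rpe_band),
                           sub(ph$labels$rpedc), g10))
}

test_that("model construction is deterministic and validates the arch", {
  cfg <- train_config(arch = "encoder_decoder", seed = 7)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$checksum, m2$checksum)
  m3 <- build_model(train_config(arch = "encoder_decoder", seed = 8))
  expect_false(identical(m1$checksum, m3$checksum))
  expect_error(train_config(arch = "resnet"), "arch")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(threshold = 1), "threshold")
})

test_that("forward pass preserves spatial shape with 3 channels", {
  for (arch in c("encoder_decoder", "dilated")) {
    m <- build_model(train_config(arch = arch, seed = 1))
    z <- retilab:::nn_forward_cpp(arch, m$params, matrix(runif(64 * 96), 64, 96))
    expect_equal(dim(z), c(64, 96, 3))
  }
})

test_that("training reduces the loss and is fully seeded", {
  fx <- seg_fixture(n_bscans = 10)
  for (arch in c("encoder_decoder", "dilated")) {
    cfg <- train_config(epochs = 3, learning_rate = 1e-4, arch = arch,
                        seed = 0, batch_size = 2)
    m <- train_model(build_model(cfg), list(fx), cfg)
    lh <- m$loss_history
    expect_equal(nrow(lh), 3)
    expect_lt(lh$mean_loss[3], lh$mean_loss[1])
    m2 <- train_model(build_model(cfg), list(fx), cfg)
    expect_identical(m$loss_history, m2$loss_history)
    expect_identical(m$checksum, m2$checksum)
  }
  expect_error(train_model(build_model(train_config()), list()), "empty")
})

test_that("all-zero labels drive predictions toward empty masks", {
  fx <- seg_fixture(n_bscans = 8)
  g <- fx$volume$grid
  z <- array(0L, c(g$n_rows, g$n_cols, g$n_bscans))
  zero <- oct_labels(z, z, z, g)
  cfg <- train_config(epochs = 5, arch = "encoder_decoder", seed = 0)
  m <- train_model(build_model(cfg), list(list(volume = fx$volume, labels = zero)), cfg)
  pred <- predict_labels(m, fx$volume)
  fg <- mean(pred$ilm_band + pred$rpe_band + pred$rpedc > 0)
  expect_lt(fg, 0.01)
})

test_that("prediction is deterministic with independent channel thresholds", {
  fx <- seg_fixture(n_bscans = 6)
  cfg <- train_config(epochs = 2, learning_rate = 1e-4, arch = "dilated", seed = 2)
  m <- train_model(build_model(cfg), list(fx), cfg)
  p1 <- predict_labels(m, fx$volume)
  p2 <- predict_labels(m, fx$volume)
  expect_identical(p1$ilm_band, p2$ilm_band)
  expect_identical(p1$rpedc, p2$rpedc)
  # changing the threshold re-derives every channel from its own scores only:
  # channels with identical scores under two thresholds nest monotonically
  lo <- predict_labels(m, fx$volume, threshold = 0.3)
  hi <- predict_labels(m, fx$volume, threshold = 0.7)
  for (ch in c("ilm_band", "rpe_band", "rpedc")) {
    expect_true(all(hi[[ch]] <= lo[[ch]]))
  }
  expect_error(predict_labels(m, fx$volume, threshold = 0), "threshold")
})

test_that("the strict-threshold rule excludes scores at the boundary", {
  # logit 0 = probability exactly 0.5: strict > excludes it
  expect_identical(stats::plogis(0) > 0.5, FALSE)
  m <- build_model(train_config(arch = "dilated", seed = 3))
  # untrained net with zeroed head weights and bias gives logits exactly 0
  m$params$W[[8]][] <- 0
  m$params$b[[8]][] <- 0
  fx <- seg_fixture(n_bscans = 2)
  pred <- predict_labels(m, fx$volume, threshold = 0.5)
  expect_equal(sum(pred$ilm_band) + sum(pred$rpe_band) + sum(pred$rpedc), 0)
})

test_that("the encoder-decoder can overfit a tiny training set", {
  fx <- seg_fixture(n_bscans = 10)
  # 10 B-scans x 20 epochs = 200 optimization steps at batch size 1
  cfg <- train_config(epochs = 20, learning_rate = 1e-4,
                      arch = "encoder_decoder", seed = 0, augment = FALSE)
  m <- train_model(build_model(cfg), list(fx), cfg)
  pred <- predict_labels(m, fx$volume)
  acc <- mean(c(pred$ilm_band == fx$labels$ilm_band,
                pred$rpe_band == fx$labels$rpe_band,
                pred$rpedc == fx$labels$rpedc))
  expect_gt(acc, 0.99)
})
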