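test_that("dice loss honours its closed-form extremes", {
  # hard one-hot prediction identical to the target
  mask <- matrix(sample(0:2, 64, TRUE), 8, 8)
  p <- meibseg:::one_hot_mask(mask)
  expect_lt(dice_loss(p, mask), 1e-5)
  # prediction disjoint from the target in every class
  shifted <- (mask + 1) %% 3
  expect_gt(dice_loss(meibseg:::one_hot_mask(shifted), mask), 1 - 1e-5)
})

test_that("dice loss matches a per-pixel counting oracle on a toy case and
           on random soft predictions", {
  # single-class arithmetic: |y|=4, |y pred|=6, overlap 3 -> 1 - 6/10
  pred <- matrix(0L, 4, 4); pred[1:6] <- 1L
  truth <- matrix(0L, 4, 4); truth[4:7] <- 1L
  p1 <- (pred == 1) * 1
  d <- (2 * sum(p1 * (truth == 1)) + 1e-6) /
       (sum(p1) + sum(truth == 1) + 1e-6)
  expect_equal(1 - d, 0.4, tolerance = 1e-6)
  set.seed(21)
  for (i in 1:30) {
    mask <- matrix(sample(0:2, 144, TRUE), 12, 12)
    raw <- array(runif(12 * 12 * 3), c(12, 12, 3))
    p <- raw / array(rep(apply(raw, c(1, 2), sum), 3), dim(raw))
    expect_equal(dice_loss(p, mask), oracle_dice_loss(p, mask),
                 tolerance = 1e-9)
  }
})

test_that("dice loss lives in [0,1] and decreases as overlap grows", {
  truth <- matrix(0L, 8, 8); truth[1:32] <- 2L
  losses <- vapply(c(0, 8, 16, 24, 32), function(k) {
    pred <- matrix(0L, 8, 8)
    if (k > 0) pred[1:k] <- 2L
    dice_loss(meibseg:::one_hot_mask(pred), truth)
  }, numeric(1))
  expect_true(all(losses >= 0 & losses <= 1))
  expect_true(all(diff(losses) < 0))
})

test_that("the L1 penalty sums absolute convolution weights only", {
  net <- build_network(network_config(width_scale = 0.0625, input_size = 64,
                                      encoder_blocks = c(1, 1, 1, 1),
                                      seed = 9))
  expect_equal(l1_penalty(net, 0), 0)
  manual <- sum(vapply(net$layers, function(ly)
    if (ly$type == "conv") sum(abs(ly$W)) else 0, numeric(1)))
  expect_equal(l1_penalty(net, 0.1), 0.1 * manual, tolerance = 1e-12)
  for (ly in net$layers) if (ly$type == "conv") ly$W[] <- 0
  expect_equal(l1_penalty(net, 0.5), 0)
  # two weights {-1, 3} at coefficient 0.1
  expect_equal(0.1 * sum(abs(c(-1, 3))), 0.4)
})

test_that("the learning-rate schedule follows its closed form", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 3e-4)
  expect_equal(lr_at_epoch(4, cfg), 3e-4)
  expect_equal(lr_at_epoch(5, cfg), 3e-4 * 0.8)
  expect_equal(lr_at_epoch(10, cfg), 3e-4 * 0.8^2)
  for (e in 0:30)
    expect_equal(lr_at_epoch(e, cfg), 3e-4 * 0.8^floor(e / 5))
})

test_that("training configuration defaults match the protocol and reject
           nonsense", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 3e-4)
  expect_equal(cfg$lr_decay_factor, 0.8)
  expect_equal(cfg$lr_decay_every, 5L)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$max_epochs, 50L)
  expect_equal(cfg$adam_beta1, 0.9)
  expect_equal(cfg$adam_beta2, 0.999)
  expect_error(train_config(learning_rate = -1), "positive")
  expect_error(fit_network(build_network(network_config(width_scale = 0.1,
                                                        input_size = 64)),
                           list()), "empty")
})

test_that("a short fit records history, decays the learning rate, and its
           loss trend is non-increasing after smoothing", {
  ph <- lapply(1:2, tiny_phantom)
  net <- build_network(network_config(width_scale = 0.1, input_size = 64,
                                      seed = 10))
  cfg <- train_config(batch_size = 2, max_epochs = 12, input_size = 64,
                      seed = 11)
  fit <- fit_network(net, ph, val_set = ph[1], config = cfg)
  h <- fit$history
  expect_equal(nrow(h), 12)
  expect_equal(h$lr, 3e-4 * 0.8^floor(0:11 / 5))
  sm <- stats::filter(h$train_loss, rep(1 / 4, 4), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.02))
  expect_s3_class(fit, "mgseg_fit")
  expect_true(is.finite(fit$best_epoch))
  pred <- predict(fit, ph[[1]])
  expect_true(all(pred %in% 0:2))
})
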