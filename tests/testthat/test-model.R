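test_that("the forward pass maps H x W input to 3-channel scores at the
           same resolution", {
  net <- build_network(network_config(width_scale = 0.1, input_size = 64,
                                      seed = 1))
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  y <- network_forward(net, x)
  expect_identical(dim(y), c(64L, 64L, 3L, 1L))
  # batched input keeps per-sample results
  xb <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  yb <- network_forward(net, xb)
  expect_identical(dim(yb), c(64L, 64L, 3L, 2L))
})

test_that("evaluation-mode forward passes are identical", {
  net <- build_network(network_config(width_scale = 0.1, input_size = 64,
                                      seed = 2))
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  expect_identical(network_forward(net, x), network_forward(net, x))
})

test_that("parameter count grows with width scale", {
  n1 <- n_parameters(build_network(network_config(width_scale = 1,
                                                  input_size = 64)))
  n2 <- n_parameters(build_network(network_config(width_scale = 0.25,
                                                  input_size = 64)))
  expect_gt(n1, n2)
})

test_that("invalid network configurations are rejected", {
  expect_error(network_config(input_size = 100), "divisible")
  expect_error(network_config(width_scale = 0), "width_scale")
  expect_error(network_config(msp_dilations = integer()), "msp_dilations")
})

test_that("dilated branches have the advertised impulse-response support", {
  expect_identical(dilated_support(1), 3L)
  expect_identical(dilated_support(2), 5L)
  expect_identical(dilated_support(3), 7L)
  # closed form 3 + 2(r-1) for good measure
  for (r in 1:4) expect_identical(dilated_support(r), 3L + 2L * (r - 1L))
})

test_that("the MSP block preserves spatial dimensions and maps zero to zero", {
  msp <- meibseg:::msp_block(8, c(1, 2, 3))
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  y <- msp_forward(msp, x)
  expect_identical(dim(y), dim(x))
  z <- msp_forward(msp, array(0, c(16, 16, 8, 1)))
  expect_equal(max(abs(z)), 0)
})

test_that("analytic gradients agree with finite differences through the
           whole network", {
  set.seed(4)
  cfg <- network_config(width_scale = 0.0625, input_size = 64,
                        encoder_blocks = c(1, 1, 1, 1), seed = 5)
  net <- build_network(cfg)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  yl <- array(sample(0:2, 64 * 64, TRUE), c(64, 64, 1))
  lossfn <- function() {
    z <- network_forward(net, x, training = TRUE)
    p <- meibseg:::softmax_channels(z)
    meibseg:::dice_loss_parts(p, meibseg:::one_hot_mask(yl))$loss
  }
  z <- network_forward(net, x, training = TRUE)
  p <- meibseg:::softmax_channels(z)
  t1 <- meibseg:::one_hot_mask(yl)
  parts <- meibseg:::dice_loss_parts(p, t1)
  dz <- meibseg:::softmax_backward(p, meibseg:::dice_loss_grad(p, t1, parts))
  meibseg:::zero_grads(net$layers)
  meibseg:::network_backward(net, dz)
  eps <- 1e-5
  lys <- net$layers
  for (ly in lys[c(1, 2, 7, length(lys) - 2, length(lys))]) {
    for (pn in meibseg:::param_names(ly)) {
      g <- ly[[meibseg:::grad_name(pn)]]
      idx <- sample(length(ly[[pn]]), min(2, length(ly[[pn]])))
      for (i in idx) {
        v0 <- ly[[pn]][i]
        ly[[pn]][i] <- v0 + eps; lp <- lossfn()
        ly[[pn]][i] <- v0 - eps; lm <- lossfn()
        ly[[pn]][i] <- v0
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-6), 1e-3)
      }
    }
  }
})

test_that("predicted masks stay in the label alphabet and argmax logic is
           honoured", {
  net <- build_network(network_config(width_scale = 0.1, input_size = 64,
                                      seed = 6))
  ph <- tiny_phantom(7)
  pred <- predict_mask(net, ph$image)
  expect_identical(dim(pred), dim(ph$image))
  expect_true(all(pred %in% 0:2))
  # score map with channel 3 uniformly largest -> all-2 labels
  sc <- array(0, c(4, 4, 3, 1)); sc[, , 3, ] <- 5
  lab <- apply(sc[, , , 1], c(1, 2), which.max) - 1L
  expect_true(all(lab == 2))
})

test_that("networks survive a checkpoint round trip", {
  net <- build_network(network_config(width_scale = 0.1, input_size = 64,
                                      seed = 8))
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  back <- load_network(path)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  expect_equal(network_forward(back, x), network_forward(net, x),
               tolerance = 1e-12)
  expect_true(file.exists(sub("\\.rds$", "_config.json", path)))
})
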