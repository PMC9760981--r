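# Training: multi-class soft Dice loss with L1 weight regularization,
# Adam with a step-decay learning-rate schedule, and best-validation
# checkpoint selection.

softmax_channels <- function(z) {
  C <- dim(z)[3]
  m <- z[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) m <- pmax(m, z[, , c, , drop = FALSE])
  e <- z
  for (c in seq_len(C)) e[, , c, ] <- exp(z[, , c, ] - m[, , 1, ])
  s <- e[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) s <- s + e[, , c, , drop = FALSE]
  for (c in seq_len(C)) e[, , c, ] <- e[, , c, ] / s[, , 1, ]
  e
}

one_hot_mask <- function(mask, n_classes = 3L) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1)
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], n_classes, d[3]))
  for (c in seq_len(n_classes))
    out[, , c, ] <- (mask == (c - 1))
  out
}

#' Multi-class soft Dice loss
#'
#' Per-class soft Dice between predicted class probabilities and the
#' one-hot target, averaged over the 3 classes:
#' `1 - mean_c (2 |y_c ∩ y'_c| + s) / (|y_c| + |y'_c| + s)` with a small
#' smoothing constant `s` guarding against absent classes. The value lies
#' in \[0,1\]; 0 for a perfect hard prediction, 1 for complete disjointness.
#'
#' @param pred_probs `H x W x 3 x N` array of per-pixel class
#'   probabilities (summing to 1 over classes), or `H x W x 3`.
#' @param target label mask over \{0,1,2\} (`H x W` or `H x W x N`).
#' @param smooth smoothing constant (default 1e-6).
#' @return scalar loss.
#' @export
dice_loss <- function(pred_probs, target, smooth = 1e-6) {
  if (length(dim(pred_probs)) == 3) dim(pred_probs) <- c(dim(pred_probs), 1)
  t <- one_hot_mask(target, dim(pred_probs)[3])
  if (!all(dim(t) == dim(pred_probs)))
    stop_param("prediction and target shapes differ")
  dice_loss_parts(pred_probs, t, smooth)$loss
}

dice_loss_parts <- function(p, t, smooth = 1e-6) {
  C <- dim(p)[3]
  num <- den <- numeric(C)
  for (c in seq_len(C)) {
    num[c] <- 2 * sum(p[, , c, ] * t[, , c, ]) + smooth
    den[c] <- sum(p[, , c, ]) + sum(t[, , c, ]) + smooth
  }
  list(loss = 1 - mean(num / den), num = num, den = den)
}

# gradient of dice_loss w.r.t. the probability array
dice_loss_grad <- function(p, t, parts, smooth = 1e-6) {
  C <- dim(p)[3]
  g <- p
  for (c in seq_len(C))
    g[, , c, ] <- -(2 * t[, , c, ] * parts$den[c] - parts$num[c]) /
      (C * parts$den[c]^2)
  g
}

softmax_backward <- function(p, dp) {
  C <- dim(p)[3]
  s <- p[, , 1, , drop = FALSE] * dp[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1])
    s <- s + p[, , c, , drop = FALSE] * dp[, , c, , drop = FALSE]
  dz <- p
  for (c in seq_len(C)) dz[, , c, ] <- p[, , c, ] * (dp[, , c, ] - s[, , 1, ])
  dz
}

#' L1 penalty on convolution weights
#'
#' `weight` times the sum of absolute values of all convolution kernel
#' weights (biases and normalization parameters are not penalized).
#'
#' @param net an `mgseg_net`.
#' @param weight non-negative coefficient.
#' @return scalar penalty.
#' @export
l1_penalty <- function(net, weight) {
  if (weight < 0) stop_param("l1 weight must be >= 0")
  if (weight == 0) return(0)
  weight * sum(vapply(net$layers, function(ly)
    if (ly$type == "conv") sum(abs(ly$W)) else 0, numeric(1)))
}

#' Training configuration
#'
#' Defaults follow the training protocol of the segmentation study: Adam
#' with decay rates 0.9/0.999, initial learning rate 3e-4 decaying by a
#' factor 0.8 every 5 epochs, batch size 32, at most 50 epochs, Dice loss
#' plus L1 regularization, inputs resized to 256x256.
#'
#' @param learning_rate initial learning rate.
#' @param lr_decay_factor multiplicative decay.
#' @param lr_decay_every decay period, epochs.
#' @param batch_size minibatch size.
#' @param max_epochs maximum epochs.
#' @param adam_beta1,adam_beta2 Adam exponential decay rates.
#' @param l1_weight L1 coefficient on convolution weights (the study does
#'   not state a value; 1e-6 keeps the penalty a small fraction of the
#'   initial Dice loss).
#' @param input_size training resolution, pixels.
#' @param seed RNG seed (shuffling).
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, lr_decay_factor = 0.8,
                         lr_decay_every = 5L, batch_size = 32L,
                         max_epochs = 50L, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, l1_weight = 1e-6,
                         input_size = 256L, seed = 1L) {
  vals <- c(learning_rate, lr_decay_factor, lr_decay_every, batch_size,
            max_epochs, adam_beta1, adam_beta2)
  if (any(vals <= 0)) stop_param("all training parameters must be positive")
  if (l1_weight < 0) stop_param("l1_weight must be >= 0")
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 l1_weight = l1_weight, input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Closed form of the step-decay schedule:
#' `learning_rate * lr_decay_factor ^ floor(epoch / lr_decay_every)`,
#' with `epoch` counted from 0.
#'
#' @param epoch epoch index, 0-based.
#' @param config a [train_config()].
#' @return scalar learning rate.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  config$learning_rate *
    config$lr_decay_factor ^ floor(epoch / config$lr_decay_every)
}

prepare_tensor <- function(item, size) {
  img <- resize_image(item$image, size, size, "bilinear") / 255
  msk <- resize_image(item$mask, size, size, "nearest")
  list(x = img, y = matrix(as.integer(round(msk)), size, size))
}

# mean DSC over a validation set, per region (labels 1 and 2);
# images with an empty truth region are excluded per region.
validation_dsc <- function(net, val_prepared) {
  acc <- c(eyelid = 0, mg = 0); cnt <- c(eyelid = 0, mg = 0)
  for (it in val_prepared) {
    sc <- network_forward(net, array(it$x, c(dim(it$x), 1, 1)))
    pred <- apply(sc[, , , 1], c(1, 2), which.max) - 1L
    for (r in 1:2) {
      m <- region_metrics(pred, it$y, r)
      key <- if (r == 1) "eyelid" else "mg"
      if (!m$flagged) { acc[key] <- acc[key] + m$dsc; cnt[key] <- cnt[key] + 1 }
    }
  }
  ifelse(cnt > 0, acc / cnt, NA_real_)
}

#' Train the segmentation network
#'
#' Minimizes Dice loss plus the L1 penalty with Adam under the step-decay
#' schedule, recording per-epoch training loss, learning rate, and
#' validation DSC per region. The returned model carries the parameters of
#' the epoch with the best mean validation DSC (final parameters when no
#' validation set is given).
#'
#' @param net an `mgseg_net` from [build_network()].
#' @param train_set,val_set lists of `labeled_image` objects (`val_set`
#'   may be `NULL`).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `mgseg_fit`: list with `network`, `history`
#'   (data frame), `config`, `best_epoch`.
#' @export
fit_network <- function(net, train_set, val_set = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "mgseg_net"), inherits(config, "train_config"))
  if (length(train_set) == 0) stop_param("training set is empty")
  size <- config$input_size
  tr <- lapply(train_set, prepare_tensor, size = size)
  va <- if (length(val_set)) lapply(val_set, prepare_tensor, size = size)
  hist <- list()
  best <- -Inf; best_snap <- NULL; best_epoch <- NA_integer_
  step <- 0L
  with_seed(config$seed, {
    for (epoch in 0:(config$max_epochs - 1)) {
      lr <- lr_at_epoch(epoch, config)
      ord <- sample(length(tr))
      losses <- c()
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        x <- array(0, c(size, size, 1, length(idx)))
        y <- array(0L, c(size, size, length(idx)))
        for (j in seq_along(idx)) {
          x[, , 1, j] <- tr[[idx[j]]]$x
          y[, , j] <- tr[[idx[j]]]$y
        }
        z <- network_forward(net, x, training = TRUE)
        p <- softmax_channels(z)
        t1 <- one_hot_mask(y)
        parts <- dice_loss_parts(p, t1)
        loss <- parts$loss + l1_penalty(net, config$l1_weight)
        dz <- softmax_backward(p, dice_loss_grad(p, t1, parts))
        zero_grads(net$layers)
        network_backward(net, dz)
        if (config$l1_weight > 0)
          for (ly in net$layers)
            if (ly$type == "conv" && !is.null(ly$dW))
              ly$dW <- ly$dW + config$l1_weight * sign(ly$W)
        step <- step + 1L
        adam_step(net$layers, lr, config$adam_beta1, config$adam_beta2,
                  t = step)
        losses <- c(losses, loss)
      }
      vd <- if (!is.null(va)) validation_dsc(net, va) else c(NA, NA)
      hist[[epoch + 1]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        val_dsc_eyelid = vd[1], val_dsc_mg = vd[2])
      if (verbose)
        message(sprintf("epoch %2d lr %.2e loss %.4f val DSC eyelid %.3f mg %.3f",
                        epoch, lr, mean(losses), vd[1], vd[2]))
      score <- mean(vd, na.rm = TRUE)
      if (!is.null(va) && is.finite(score) && score > best) {
        best <- score; best_snap <- snapshot_params(net$layers)
        best_epoch <- epoch
      }
    }
  })
  if (!is.null(best_snap)) restore_params(net$layers, best_snap)
  structure(list(network = net, history = do.call(rbind, hist),
                 config = config, best_epoch = best_epoch),
            class = "mgseg_fit")
}

#' @export
print.mgseg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("<mgseg_fit> %d epochs, final train loss %.4f",
                     "%s\n"),
              nrow(h), h$train_loss[nrow(h)],
              if (!is.na(x$best_epoch))
                sprintf(", best val DSC at epoch %d (eyelid %.3f, MG %.3f)",
                        x$best_epoch, h$val_dsc_eyelid[x$best_epoch + 1],
                        h$val_dsc_mg[x$best_epoch + 1]) else ""))
  invisible(x)
}

#' @export
predict.mgseg_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_image")) newdata <- newdata$image
  predict_mask(object$network, newdata)
}

#' @export
plot.mgseg_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "Dice loss", main = "training history", ...)
  if (any(is.finite(h$val_dsc_mg))) {
    graphics::lines(h$epoch, 1 - h$val_dsc_mg, lty = 2)
    graphics::legend("topright", c("train loss", "1 - val MG DSC"),
                     lty = 1:2, bty = "n")
  }
  invisible(x)
}
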