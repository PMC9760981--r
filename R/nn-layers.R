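# Minimal CNN engine used by the segmentation network: convolution (via
# compiled im2col/GEMM kernels), batch normalization, ReLU, max pooling and
# bilinear upsampling, each with an explicit backward pass, plus Adam.
# Tensors are H x W x C x N arrays. Layers are environments that cache
# whatever their backward pass needs.

new_conv <- function(cin, cout, k, stride = 1L, pad = NULL, dilation = 1L,
                     init_gain = 2) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad %||% (dilation * (k - 1) / 2))
  ly$dilation <- as.integer(dilation)
  # He-style initialization for ReLU networks
  ly$W <- array(stats::rnorm(k * k * cin * cout, 0,
                             sqrt(init_gain / (k * k * cin))),
                c(k, k, cin, cout))
  ly$b <- numeric(cout)
  ly
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"
  ly$gamma <- rep(1, c); ly$beta <- rep(0, c)
  ly$run_mean <- rep(0, c); ly$run_var <- rep(1, c)
  ly$momentum <- momentum; ly$eps <- eps
  ly
}

new_relu <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "relu"; ly
}

new_pool <- function(k = 3L, stride = 2L, pad = 1L) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "pool"; ly$k <- k; ly$stride <- stride; ly$pad <- pad
  ly
}

new_upsample <- function(scale = 2L) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "up"; ly$scale <- as.integer(scale)
  ly
}

# align-corners bilinear interpolation matrix (n_out x n_in)
interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1) { A[, 1] <- 1; return(A) }
  pos <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(pos), n_in - 2)
  wt <- pos - i0
  for (i in seq_len(n_out)) {
    A[i, i0[i] + 1] <- A[i, i0[i] + 1] + (1 - wt[i])
    A[i, i0[i] + 2] <- A[i, i0[i] + 2] + wt[i]
  }
  A
}

# y = A %*% x %*% t(B) applied per channel/sample of a 4-D tensor
apply_sep <- function(x, A, B) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  H2 <- nrow(A); W2 <- nrow(B)
  dim(x) <- c(H, W * C * N)
  y <- A %*% x                        # H2 x (W*C*N)
  dim(y) <- c(H2, W, C, N)
  y <- aperm(y, c(2, 1, 3, 4))
  dim(y) <- c(W, H2 * C * N)
  y <- B %*% y                        # W2 x (H2*C*N)
  dim(y) <- c(W2, H2, C, N)
  aperm(y, c(2, 1, 3, 4))
}

layer_fwd <- function(ly, x, training = FALSE) {
  switch(ly$type,
    conv = {
      ly$x <- x
      conv2d_forward(x, ly$W, ly$b, ly$stride, ly$pad, ly$dilation)
    },
    bn = {
      d <- dim(x); C <- d[3]; m <- d[1] * d[2] * d[4]
      xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(m, C)
      if (training) {
        mu <- colMeans(xm)
        xc <- sweep(xm, 2, mu)
        va <- colMeans(xc * xc)
        ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
        ly$run_var  <- (1 - ly$momentum) * ly$run_var  + ly$momentum * va
      } else {
        mu <- ly$run_mean; va <- ly$run_var
        xc <- sweep(xm, 2, mu)
      }
      invstd <- 1 / sqrt(va + ly$eps)
      xhat <- sweep(xc, 2, invstd, `*`)
      y <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
      if (training) { ly$xhat <- xhat; ly$invstd <- invstd; ly$dims <- d }
      dim(y) <- c(d[1], d[2], d[4], d[3])
      aperm(y, c(1, 2, 4, 3))
    },
    relu = {
      ly$mask <- x > 0
      x * ly$mask
    },
    pool = {
      ly$in_dim <- dim(x)
      r <- maxpool_forward(x, ly$k, ly$stride, ly$pad)
      ly$argmax <- r$argmax
      r$y
    },
    up = {
      d <- dim(x); s <- ly$scale
      if (is.null(ly$A) || nrow(ly$A) != s * d[1] || ncol(ly$A) != d[1]) {
        ly$A <- interp_matrix(d[1], s * d[1])
        ly$B <- interp_matrix(d[2], s * d[2])
      }
      apply_sep(x, ly$A, ly$B)
    },
    stop("unknown layer type ", ly$type))
}

layer_bwd <- function(ly, dy) {
  switch(ly$type,
    conv = {
      g <- conv2d_backward(ly$x, ly$W, dy, ly$stride, ly$pad, ly$dilation)
      ly$dW <- (ly$dW %||% 0) + g$dw
      ly$db <- (ly$db %||% 0) + g$db
      ly$x <- NULL
      g$dx
    },
    bn = {
      d <- ly$dims; C <- d[3]; m <- d[1] * d[2] * d[4]
      dym <- aperm(dy, c(1, 2, 4, 3)); dim(dym) <- c(m, C)
      ly$dgamma <- (ly$dgamma %||% 0) + colSums(dym * ly$xhat)
      ly$dbeta <- (ly$dbeta %||% 0) + colSums(dym)
      dxhat <- sweep(dym, 2, ly$gamma, `*`)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * ly$xhat)
      dx <- sweep(dxhat, 2, s1 / m) - sweep(ly$xhat, 2, s2 / m, `*`)
      dx <- sweep(dx, 2, ly$invstd, `*`)
      dim(dx) <- c(d[1], d[2], d[4], d[3])
      ly$xhat <- NULL
      aperm(dx, c(1, 2, 4, 3))
    },
    relu = dy * ly$mask,
    pool = maxpool_backward(dy, ly$argmax, ly$in_dim),
    up = apply_sep(dy, t(ly$A), t(ly$B)),
    stop("unknown layer type ", ly$type))
}

is_param_layer <- function(ly) ly$type %in% c("conv", "bn")

zero_grads <- function(layers) {
  for (ly in layers) {
    if (ly$type == "conv") { ly$dW <- NULL; ly$db <- NULL }
    if (ly$type == "bn") { ly$dgamma <- NULL; ly$dbeta <- NULL }
  }
  invisible(NULL)
}

param_names <- function(ly) {
  if (ly$type == "conv") c("W", "b") else c("gamma", "beta")
}

grad_name <- function(p) {
  c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")[[p]]
}

adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1) {
  for (ly in layers) {
    for (p in param_names(ly)) {
      g <- ly[[grad_name(p)]]
      if (is.null(g)) next
      mkey <- paste0("m_", p); vkey <- paste0("v_", p)
      m <- (ly[[mkey]] %||% 0) * beta1 + (1 - beta1) * g
      v <- (ly[[vkey]] %||% 0) * beta2 + (1 - beta2) * g * g
      ly[[mkey]] <- m; ly[[vkey]] <- v
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      ly[[p]] <- ly[[p]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  invisible(NULL)
}

# snapshot / restore all parameters and running statistics
snapshot_params <- function(layers) {
  lapply(layers, function(ly) {
    keys <- c(param_names(ly), if (ly$type == "bn") c("run_mean", "run_var"))
    stats::setNames(lapply(keys, function(k) ly[[k]]), keys)
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers))
    for (k in names(snap[[i]])) layers[[i]][[k]] <- snap[[i]][[k]]
  invisible(NULL)
}
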