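# The segmentation network: a U-Net-style encoder-decoder with a
# 34-layer-style residual encoder (stem + stages of 3/4/6/3 basic blocks,
# no fully connected layers), a multi-scale perception (MSP) bottleneck of
# parallel dilated 3x3 convolutions fused by a 1x1 convolution, and a
# bilinear-upsampling decoder with skip concatenations, ending in a 1x1
# convolution onto 3 classes (background / eyelid / MG).

#' Network configuration
#'
#' @param in_channels input channels (grayscale meibography: 1).
#' @param n_classes number of output classes; fixed at 3.
#' @param base_width channels of the first encoder stage before scaling
#'   (64 reproduces the standard 34-layer residual backbone).
#' @param encoder_blocks residual blocks per stage.
#' @param msp_dilations dilation rates of the parallel 3x3 bottleneck
#'   convolutions; rates 1, 2, 3 give effective 3x3, 5x5 and 7x7 kernels.
#' @param width_scale multiplies all channel counts, in (0,1\]; small
#'   values allow CPU-scale training with the same architecture.
#' @param input_size square input resolution; must be divisible by 32
#'   (the total encoder stride).
#' @param decoder_steps `"x2"` (default) uses five 2x bilinear upsampling
#'   steps so every skip concatenation meets a matching resolution;
#'   `"x4"` uses 4x/4x/2x steps with skips at the resolutions that remain
#'   available.
#' @param seed RNG seed for weight initialization.
#' @return object of class `network_config`.
#' @export
network_config <- function(in_channels = 1L, n_classes = 3L, base_width = 64L,
                           encoder_blocks = c(3L, 4L, 6L, 3L),
                           msp_dilations = c(1L, 2L, 3L),
                           width_scale = 1, input_size = 256L,
                           decoder_steps = c("x2", "x4"), seed = 1L) {
  decoder_steps <- match.arg(decoder_steps)
  if (n_classes != 3L) stop_param("n_classes is fixed at 3")
  if (length(msp_dilations) < 1 || any(msp_dilations < 1))
    stop_param("msp_dilations must be positive integers")
  if (width_scale <= 0 || width_scale > 1)
    stop_param("width_scale must lie in (0,1]")
  if (input_size %% 32 != 0)
    stop_param("input_size %d is not divisible by the total encoder stride 32",
               input_size)
  structure(list(in_channels = as.integer(in_channels), n_classes = 3L,
                 base_width = as.integer(base_width),
                 encoder_blocks = as.integer(encoder_blocks),
                 msp_dilations = as.integer(msp_dilations),
                 width_scale = width_scale,
                 input_size = as.integer(input_size),
                 decoder_steps = decoder_steps, seed = as.integer(seed)),
            class = "network_config")
}

res_block <- function(cin, cout, stride) {
  blk <- list(conv1 = new_conv(cin, cout, 3, stride = stride),
              bn1 = new_bn(cout), relu1 = new_relu(),
              conv2 = new_conv(cout, cout, 3), bn2 = new_bn(cout),
              relu2 = new_relu())
  if (stride != 1 || cin != cout) {
    blk$proj <- new_conv(cin, cout, 1, stride = stride, pad = 0)
    blk$bnp <- new_bn(cout)
  }
  blk
}

block_fwd <- function(blk, x, training) {
  y <- layer_fwd(blk$conv1, x, training)
  y <- layer_fwd(blk$bn1, y, training)
  y <- layer_fwd(blk$relu1, y, training)
  y <- layer_fwd(blk$conv2, y, training)
  y <- layer_fwd(blk$bn2, y, training)
  sc <- x
  if (!is.null(blk$proj)) {
    sc <- layer_fwd(blk$proj, x, training)
    sc <- layer_fwd(blk$bnp, sc, training)
  }
  layer_fwd(blk$relu2, y + sc, training)
}

block_bwd <- function(blk, dy) {
  d <- layer_bwd(blk$relu2, dy)
  dsc <- d
  dm <- layer_bwd(blk$bn2, d)
  dm <- layer_bwd(blk$conv2, dm)
  dm <- layer_bwd(blk$relu1, dm)
  dm <- layer_bwd(blk$bn1, dm)
  dm <- layer_bwd(blk$conv1, dm)
  if (!is.null(blk$proj)) {
    dsc <- layer_bwd(blk$bnp, dsc)
    dsc <- layer_bwd(blk$proj, dsc)
  }
  dm + dsc
}

#' Multi-scale perception block
#'
#' Parallel 3x3 convolutions with the given dilation rates (each followed
#' by ReLU), concatenated and fused by a 1x1 convolution with ReLU. With
#' rates 1, 2 and 3 the branches realise effective 3x3, 5x5 and 7x7
#' receptive fields at the cost of 3x3 kernels. Padding preserves the
#' spatial size.
#'
#' @param channels input (= output) channel count.
#' @param dilations positive integer dilation rates.
#' @return an `msp_block` object.
#' @export
msp_block <- function(channels, dilations = c(1L, 2L, 3L)) {
  branches <- lapply(dilations, function(d)
    list(conv = new_conv(channels, channels, 3, dilation = d),
         relu = new_relu()))
  structure(list(branches = branches,
                 fuse = new_conv(channels * length(dilations), channels, 1,
                                 pad = 0),
                 fuse_relu = new_relu(), dilations = as.integer(dilations)),
            class = "msp_block")
}

#' Forward pass of the multi-scale perception block
#'
#' @param msp an [msp_block()].
#' @param features `H x W x C x N` array (a bare `H x W x C` array is
#'   promoted to batch size 1).
#' @param training propagate in training mode (caches for backward).
#' @return array of the same spatial dimensions and `C` channels.
#' @export
msp_forward <- function(msp, features, training = FALSE) {
  if (length(dim(features)) == 3) dim(features) <- c(dim(features), 1)
  outs <- lapply(msp$branches, function(br) {
    y <- layer_fwd(br$conv, features, training)
    layer_fwd(br$relu, y, training)
  })
  cat_ <- concat_channels(outs)
  y <- layer_fwd(msp$fuse, cat_, training)
  layer_fwd(msp$fuse_relu, y, training)
}

msp_backward <- function(msp, dy) {
  d <- layer_bwd(msp$fuse_relu, dy)
  d <- layer_bwd(msp$fuse, d)
  parts <- split_channels(d, vapply(msp$branches, function(br)
    dim(br$conv$W)[4], integer(1)))
  dx <- 0
  for (i in seq_along(msp$branches)) {
    db <- layer_bwd(msp$branches[[i]]$relu, parts[[i]])
    dx <- dx + layer_bwd(msp$branches[[i]]$conv, db)
  }
  dx
}

concat_channels <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0
  for (x in xs) {
    out[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0
  lapply(sizes, function(s) {
    out <- x[, , at + seq_len(s), , drop = FALSE]
    at <<- at + s
    out
  })
}

decoder_plan <- function(cfg, w) {
  if (cfg$decoder_steps == "x2")
    list(list(scale = 2, skip = "s3", out = 4 * w),
         list(scale = 2, skip = "s2", out = 2 * w),
         list(scale = 2, skip = "s1", out = w),
         list(scale = 2, skip = "stem", out = w),
         list(scale = 2, skip = NULL, out = w))
  else
    list(list(scale = 4, skip = "s2", out = 2 * w),
         list(scale = 4, skip = "stem", out = w),
         list(scale = 2, skip = NULL, out = w))
}

#' Build the segmentation network
#'
#' @param config a [network_config()].
#' @return object of class `mgseg_net`.
#' @examples
#' net <- build_network(network_config(width_scale = 0.25, input_size = 64))
#' net
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  with_seed(config$seed, {
    w <- max(4L, as.integer(round(config$base_width * config$width_scale)))
    chans <- w * c(1L, 2L, 4L, 8L)
    net <- new.env(parent = emptyenv())
    net$config <- config
    net$width <- w
    net$stem_conv <- new_conv(config$in_channels, w, 7, stride = 2, pad = 3)
    net$stem_bn <- new_bn(w); net$stem_relu <- new_relu()
    net$pool <- new_pool()
    net$stages <- vector("list", 4)
    cin <- w
    for (s in 1:4) {
      nb <- config$encoder_blocks[s]
      stride1 <- if (s == 1) 1L else 2L
      blocks <- vector("list", nb)
      for (b in seq_len(nb)) {
        blocks[[b]] <- res_block(if (b == 1) cin else chans[s], chans[s],
                                 if (b == 1) stride1 else 1L)
      }
      net$stages[[s]] <- blocks
      cin <- chans[s]
    }
    net$msp <- msp_block(chans[4], config$msp_dilations)
    plan <- decoder_plan(config, w)
    skip_ch <- c(stem = w, s1 = chans[1], s2 = chans[2], s3 = chans[3])
    net$dec <- vector("list", length(plan))
    cin <- chans[4]
    for (i in seq_along(plan)) {
      st <- plan[[i]]
      cat_in <- cin + if (is.null(st$skip)) 0L else skip_ch[[st$skip]]
      net$dec[[i]] <- list(
        up = new_upsample(st$scale),
        conv1 = new_conv(cat_in, st$out, 3), bn1 = new_bn(st$out),
        relu1 = new_relu(),
        conv2 = new_conv(st$out, st$out, 3), bn2 = new_bn(st$out),
        relu2 = new_relu(),
        skip = st$skip)
      cin <- st$out
    }
    net$head <- new_conv(cin, config$n_classes, 1, pad = 0)
    net$layers <- collect_layers(net)
    class(net) <- "mgseg_net"
    net
  })
}

collect_layers <- function(net) {
  out <- list(net$stem_conv, net$stem_bn)
  for (st in net$stages)
    for (blk in st) {
      out <- c(out, list(blk$conv1, blk$bn1, blk$conv2, blk$bn2))
      if (!is.null(blk$proj)) out <- c(out, list(blk$proj, blk$bnp))
    }
  for (br in net$msp$branches) out <- c(out, list(br$conv))
  out <- c(out, list(net$msp$fuse))
  for (d in net$dec)
    out <- c(out, list(d$conv1, d$bn1, d$conv2, d$bn2))
  c(out, list(net$head))
}

#' Total number of trainable parameters
#' @param net an `mgseg_net`.
#' @return integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(ly)
    sum(vapply(param_names(ly), function(p) length(ly[[p]]), numeric(1))),
    numeric(1)))
}

#' @export
print.mgseg_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<mgseg_net> residual U-Net, width %d (scale %.2f), ",
                     "stages %s, MSP dilations %s, input %dx%d, ",
                     "%s parameters\n"),
              x$width, cfg$width_scale,
              paste(cfg$encoder_blocks, collapse = "-"),
              paste(cfg$msp_dilations, collapse = ","),
              cfg$input_size, cfg$input_size,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Full forward pass
#'
#' @param net an `mgseg_net`.
#' @param x `H x W x Cin x N` array of intensities scaled to \[0,1\]
#'   (a bare matrix is promoted to a single-sample batch).
#' @param training run in training mode (batch statistics, caches kept for
#'   the backward pass).
#' @return class-score array `H x W x n_classes x N` at the input
#'   resolution.
#' @export
network_forward <- function(net, x, training = FALSE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1, 1)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  a <- layer_fwd(net$stem_conv, x, training)
  a <- layer_fwd(net$stem_bn, a, training)
  stem <- layer_fwd(net$stem_relu, a, training)
  a <- layer_fwd(net$pool, stem, training)
  skips <- list(stem = stem)
  for (s in 1:4) {
    for (blk in net$stages[[s]]) a <- block_fwd(blk, a, training)
    skips[[paste0("s", s)]] <- a
  }
  a <- msp_forward(net$msp, a, training)
  for (d in net$dec) {
    a <- layer_fwd(d$up, a, training)
    if (!is.null(d$skip)) a <- concat_channels(list(a, skips[[d$skip]]))
    a <- layer_fwd(d$conv1, a, training)
    a <- layer_fwd(d$bn1, a, training)
    a <- layer_fwd(d$relu1, a, training)
    a <- layer_fwd(d$conv2, a, training)
    a <- layer_fwd(d$bn2, a, training)
    a <- layer_fwd(d$relu2, a, training)
  }
  layer_fwd(net$head, a, training)
}

network_backward <- function(net, dscores) {
  da <- layer_bwd(net$head, dscores)
  dskips <- list()
  for (i in rev(seq_along(net$dec))) {
    d <- net$dec[[i]]
    da <- layer_bwd(d$relu2, da)
    da <- layer_bwd(d$bn2, da)
    da <- layer_bwd(d$conv2, da)
    da <- layer_bwd(d$relu1, da)
    da <- layer_bwd(d$bn1, da)
    da <- layer_bwd(d$conv1, da)
    if (!is.null(d$skip)) {
      nskip <- skip_channels_of(net, d$skip)
      parts <- split_channels(da, c(dim(da)[3] - nskip, nskip))
      dskips[[d$skip]] <- (dskips[[d$skip]] %||% 0) + parts[[2]]
      da <- parts[[1]]
    }
    da <- layer_bwd(d$up, da)
  }
  da <- msp_backward(net$msp, da)
  for (s in 4:1) {
    if (!is.null(dskips[[paste0("s", s)]]))
      da <- da + dskips[[paste0("s", s)]]
    for (blk in rev(net$stages[[s]])) da <- block_bwd(blk, da)
  }
  da <- layer_bwd(net$pool, da)
  if (!is.null(dskips$stem)) da <- da + dskips$stem
  da <- layer_bwd(net$stem_relu, da)
  da <- layer_bwd(net$stem_bn, da)
  layer_bwd(net$stem_conv, da)
}

skip_channels_of <- function(net, skip) {
  chans <- net$width * c(1L, 2L, 4L, 8L)
  switch(skip, stem = net$width, s1 = chans[1], s2 = chans[2], s3 = chans[3])
}

#' Effective kernel extent of a dilated 3x3 convolution
#'
#' Measures the support of the impulse response empirically: a 3x3
#' convolution with unit weights and zero bias at the given dilation rate
#' is applied to a centred single-pixel impulse, and the side length of
#' the nonzero output region is returned. Rates 1, 2 and 3 give 3, 5 and
#' 7 pixels.
#'
#' @param dilation dilation rate (>= 1).
#' @param k kernel size (default 3).
#' @return integer support width in pixels.
#' @export
dilated_support <- function(dilation, k = 3L) {
  ly <- new_conv(1, 1, k, dilation = dilation)
  ly$W[] <- 1; ly$b[] <- 0
  n <- 4 * dilation * k + 1
  x <- array(0, c(n, n, 1, 1)); x[(n + 1) / 2, (n + 1) / 2, 1, 1] <- 1
  y <- layer_fwd(ly, x)[, , 1, 1]
  rows <- range(which(rowSums(y != 0) > 0))
  cols <- range(which(colSums(y != 0) > 0))
  as.integer(max(diff(rows), diff(cols)) + 1L)
}

#' Predict a segmentation mask for one image
#'
#' The image is rescaled to the network's input size, passed through the
#' network, the per-pixel argmax over the 3 class scores is taken, and the
#' label map is resized back to the original dimensions with
#' nearest-neighbour interpolation.
#'
#' @param net an `mgseg_net` (or `mgseg_fit`).
#' @param image 8-bit grayscale matrix.
#' @return integer label matrix over \{0,1,2\} with `dim(image)`.
#' @export
predict_mask <- function(net, image) {
  if (inherits(net, "mgseg_fit")) net <- net$network
  check_uint8(image)
  s <- net$config$input_size
  x <- resize_image(image, s, s, "bilinear") / 255
  sc <- network_forward(net, matrix(x, s, s), training = FALSE)
  lab <- apply(sc[, , , 1], c(1, 2), which.max) - 1L
  out <- resize_image(lab, nrow(image), ncol(image), "nearest")
  matrix(as.integer(round(out)), nrow(image), ncol(image))
}

#' Persist / restore a network
#'
#' Weights are stored with `saveRDS`; a JSON sidecar records the
#' configuration for inspection.
#'
#' @param net an `mgseg_net`.
#' @param path checkpoint path (`.rds`).
#' @return `load_network` returns an `mgseg_net`.
#' @export
save_network <- function(net, path) {
  snap <- snapshot_params(net$layers)
  saveRDS(list(config = unclass(net$config), params = snap), path)
  jsonlite::write_json(unclass(net$config),
                       paste0(sub("\\.rds$", "", path), "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(network_config, obj$config)
  net <- build_network(cfg)
  restore_params(net$layers, obj$params)
  net
}
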