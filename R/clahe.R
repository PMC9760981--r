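# Contrast-limited adaptive histogram equalization. Tile-wise histogram
# equalization with a clip limit (excess redistributed uniformly) and
# bilinear interpolation between neighbouring tile mappings, which removes
# tile-boundary artifacts while limiting noise amplification.

#' CLAHE parameters
#'
#' @param tile_size side length of the square local region, pixels
#'   (>= 8; the default 64 matches the neighbourhood-block size commonly
#'   used for meibography enhancement).
#' @param clip_limit histogram clip limit as a multiple of the mean bin
#'   height of a tile histogram; > 0. Large values disable clipping and
#'   recover plain adaptive equalization.
#' @return object of class `clahe_params`.
#' @export
clahe_params <- function(tile_size = 64, clip_limit = 2.0) {
  if (tile_size < 8) stop_param("tile_size must be >= 8")
  if (clip_limit <= 0) stop_param("clip_limit must be > 0")
  structure(list(tile_size = as.integer(tile_size), clip_limit = clip_limit),
            class = "clahe_params")
}

# Equalization mapping (0..255 -> 0..255) from a clipped histogram.
clahe_tile_map <- function(counts, clip_limit) {
  npix <- sum(counts)
  clip <- clip_limit * npix / 256
  excess <- sum(pmax(counts - clip, 0))
  counts <- pmin(counts, clip) + excess / 256
  round(255 * cumsum(counts) / npix)
}

#' Contrast-limited adaptive histogram equalization
#'
#' @param image 8-bit matrix.
#' @param params a [clahe_params()]. `tile_size` must not exceed either
#'   image dimension.
#' @return 8-bit matrix of the same dimensions. A constant image is
#'   returned unchanged (equalizing a single-bin histogram is taken as the
#'   identity).
#' @export
clahe <- function(image, params = clahe_params()) {
  check_uint8(image)
  stopifnot(inherits(params, "clahe_params"))
  h <- nrow(image); w <- ncol(image); ts <- params$tile_size
  if (ts > h || ts > w)
    stop_param("tile_size %d exceeds image dimensions %dx%d", ts, h, w)
  if (length(unique(as.vector(image))) == 1L) return(image)

  nty <- max(1L, round(h / ts)); ntx <- max(1L, round(w / ts))
  # tile boundaries covering the image exactly
  ye <- round(seq(0, h, length.out = nty + 1))
  xe <- round(seq(0, w, length.out = ntx + 1))
  maps <- array(0, c(nty, ntx, 256))
  cy <- numeric(nty); cx <- numeric(ntx)
  for (i in seq_len(nty)) for (j in seq_len(ntx)) {
    tile <- image[(ye[i] + 1):ye[i + 1], (xe[j] + 1):xe[j + 1], drop = FALSE]
    maps[i, j, ] <- clahe_tile_map(hist256(tile), params$clip_limit)
  }
  cy <- (ye[-1] + ye[-(nty + 1)] + 1) / 2   # tile center rows
  cx <- (xe[-1] + xe[-(ntx + 1)] + 1) / 2

  # bilinear interpolation between the four surrounding tile mappings
  ri <- findInterval(seq_len(h), cy)            # lower tile row (0..nty)
  rj <- findInterval(seq_len(w), cx)
  i0 <- pmax(ri, 1L); i1 <- pmin(ri + 1L, nty)
  j0 <- pmax(rj, 1L); j1 <- pmin(rj + 1L, ntx)
  wy <- ifelse(i1 > i0, (seq_len(h) - cy[i0]) / (cy[i1] - cy[i0]), 0)
  wx <- ifelse(j1 > j0, (seq_len(w) - cx[j0]) / (cx[j1] - cx[j0]), 0)
  wy <- pmin(pmax(wy, 0), 1); wx <- pmin(pmax(wx, 0), 1)

  v <- as.integer(image) + 1L                   # 1..256 per pixel
  idx <- function(ti, tj) {
    # maps[ti, tj, v] for per-pixel tile indices (recycled over columns)
    TI <- rep(ti, times = w); TJ <- rep(tj, each = h)
    maps[cbind(TI, TJ, v)]
  }
  WY <- rep(wy, times = w); WX <- rep(wx, each = h)
  out <- (1 - WY) * (1 - WX) * idx(i0, j0) +
         (1 - WY) * WX       * idx(i0, j1) +
         WY       * (1 - WX) * idx(i1, j0) +
         WY       * WX       * idx(i1, j1)
  matrix(clamp8(out), h, w)
}
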