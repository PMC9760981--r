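# Shared low-level helpers: validation, 8-bit conversion, resizing.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_uint8 <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_param("%s must be a numeric matrix", what)
  if (any(img < 0 | img > 255) || any(img != round(img)))
    stop_param("%s must hold 8-bit integer intensities in [0,255]", what)
  invisible(img)
}

check_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1, 2)))
    stop_param("%s must be a matrix over labels {0,1,2}", what)
  invisible(mask)
}

clamp8 <- function(x) pmin(pmax(round(x), 0), 255)

#' Resize a 2-D intensity image or label mask
#'
#' Bilinear interpolation for intensity images, nearest-neighbour for label
#' masks (labels must never be averaged).
#'
#' @param img numeric matrix.
#' @param h,w target dimensions in pixels.
#' @param method `"bilinear"` or `"nearest"`.
#' @return a numeric matrix of dimension `h` x `w`.
#' @export
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(img) == h && ncol(img) == w) return(img)
  filt <- if (method == "bilinear") "bilinear" else "none"
  # EBImage indexes dim 1 as "w"; we pass our row dimension there, which
  # makes the call a plain axis-wise rescale of the matrix.
  out <- EBImage::resize(img, w = h, h = w, filter = filt)
  matrix(as.numeric(out), nrow = h, ncol = w)
}

# Deterministic per-item seed derived from a master seed and a counter,
# kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 * 69069 + i * 104729) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 256-bin intensity histogram of an 8-bit image, as counts.
hist256 <- function(img) {
  tabulate(as.integer(img) + 1L, nbins = 256L)
}
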