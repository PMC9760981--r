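# Cross-device harmonization operators: averaged histogram template and
# histogram specification (HS). Each image of the deployment-device set is
# remapped so its intensity distribution matches the average histogram of
# the training-device population.

as_image_list <- function(images) {
  if (is.matrix(images)) return(list(images))
  lapply(images, function(x) if (inherits(x, "labeled_image")) x$image else x)
}

#' Average intensity histogram of an image population
#'
#' Each image's 256-bin histogram is normalized to sum 1, then the
#' normalized histograms are averaged bin-wise. The result characterises a
#' device's intensity distribution and serves as the target of
#' [specify_histogram()].
#'
#' @param images list of 8-bit matrices or `labeled_image` objects.
#' @param source_set optional identifier recorded in the template.
#' @return object of class `histogram_template` with fields `bins`
#'   (length 256, sums to 1), `n_images`, `source_set`.
#' @export
average_histogram <- function(images, source_set = "unnamed") {
  imgs <- as_image_list(images)
  if (length(imgs) == 0) stop_param("image collection is empty")
  acc <- numeric(256)
  for (im in imgs) {
    check_uint8(im)
    h <- hist256(im)
    acc <- acc + h / sum(h)
  }
  structure(list(bins = acc / length(imgs), n_images = length(imgs),
                 source_set = source_set),
            class = "histogram_template")
}

#' Construct a histogram template from explicit bin masses
#' @param bins non-negative length-256 vector; normalized to sum 1.
#' @param source_set identifier.
#' @return `histogram_template`.
#' @export
histogram_template <- function(bins, source_set = "manual") {
  if (length(bins) != 256 || any(bins < 0) || sum(bins) <= 0)
    stop_param("bins must be 256 non-negative masses with positive total")
  structure(list(bins = bins / sum(bins), n_images = NA_integer_,
                 source_set = source_set),
            class = "histogram_template")
}

#' @export
print.histogram_template <- function(x, ...) {
  cat(sprintf("<histogram_template> source '%s', n_images = %s, mean level %.1f\n",
              x$source_set, x$n_images, sum((0:255) * x$bins)))
  invisible(x)
}

#' Histogram specification (HS)
#'
#' Builds the monotone look-up table composing the image's empirical CDF
#' with the generalized inverse of the template CDF: input level `v` maps
#' to the smallest target level `t` with `templateCDF(t) >= imageCDF(v)`.
#' Applying the LUT pixel-wise gives an output whose intensity distribution
#' matches the template up to quantization.
#'
#' @param image 8-bit matrix.
#' @param template a `histogram_template`.
#' @return list with `image` (remapped 8-bit matrix) and `lut` (length-256
#'   integer map over 0..255, monotone non-decreasing).
#' @examples
#' tpl <- histogram_template(rep(1/256, 256))  # flat target
#' out <- specify_histogram(matrix(rep(0:255, 4), 32, 32), tpl)
#' @export
specify_histogram <- function(image, template) {
  check_uint8(image)
  stopifnot(inherits(template, "histogram_template"))
  icdf <- cumsum(hist256(image)) / length(image)
  tcdf <- cumsum(template$bins)
  tcdf[256] <- 1  # guard against rounding just below 1
  # smallest t with tcdf[t] >= icdf[v]; findInterval on the left-open grid
  lut <- findInterval(icdf, tcdf, left.open = TRUE)  # 0-based target level
  lut <- pmin(lut, 255L)
  out <- matrix(lut[as.integer(image) + 1L], nrow(image), ncol(image))
  list(image = out, lut = as.integer(lut))
}
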