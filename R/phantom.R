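# Synthetic meibography phantoms: an eyelid band containing parallel,
# slightly tortuous gland stripes, rendered under device-specific styles
# with distinct intensity histograms. Stands in for clinical acquisitions
# so every downstream stage is testable.

#' Specification of a synthetic meibography phantom
#'
#' Healthy meibomian glands are elongated, run roughly in parallel across
#' the tarsal plate, and in atrophy recede from the distal end. The phantom
#' places `n_glands` vertical stripes with sinusoidal tortuosity inside a
#' curved eyelid band; atrophy truncates the distal portion of each stripe
#' so the mask's MG loss rate (see [mg_loss_rate()]) tracks `atrophy_frac`.
#'
#' @param height,width image dimensions in pixels (at least 64).
#' @param n_glands number of gland stripes (at least 1).
#' @param gland_width_frac fraction of the inter-gland spacing occupied by a
#'   stripe, in (0,1). Healthy lids are almost fully tiled by glands, so the
#'   default is high; the residual inter-gland septa are what remains
#'   labelled eyelid inside the band.
#' @param atrophy_frac target MG loss rate in \[0,1\].
#' @param eyelid_curvature curvature of the band's upper/lower margins
#'   (0 = straight band).
#' @param noise_sigma additive Gaussian noise, 8-bit intensity units.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256, width = 256, n_glands = 12,
                         gland_width_frac = 0.985, atrophy_frac = 0,
                         eyelid_curvature = 0.12, noise_sigma = 6,
                         seed = 1L) {
  if (height < 64 || width < 64)
    stop_param("phantom dimensions must be at least 64x64 (got %dx%d)",
               height, width)
  if (atrophy_frac < 0 || atrophy_frac > 1)
    stop_param("atrophy_frac must lie in [0,1]")
  if (n_glands < 1) stop_param("n_glands must be >= 1")
  if (gland_width_frac <= 0 || gland_width_frac >= 1)
    stop_param("gland_width_frac must lie in (0,1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_glands = as.integer(n_glands),
                 gland_width_frac = gland_width_frac,
                 atrophy_frac = atrophy_frac,
                 eyelid_curvature = eyelid_curvature,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Acquisition-device rendering style
#'
#' Two meibography devices produce populations with markedly different
#' grayscale histograms. A style is a monotone tone curve plus global
#' brightness/contrast, vignetting, and sensor noise, applied to the ideal
#' phantom rendering; it changes intensities only, never the label mask.
#'
#' @param name identifier.
#' @param tone_curve numeric vector of length 256 mapping \[0,255\] to
#'   \[0,255\], monotone non-decreasing.
#' @param base_intensity additive offset (8-bit units).
#' @param contrast_gain multiplicative gain around mid-gray.
#' @param vignette_strength 0 disables; 1 darkens corners to black.
#' @param noise_sigma device noise in 8-bit units.
#' @return an object of class `device_style`.
#' @export
device_style <- function(name, tone_curve = 0:255, base_intensity = 0,
                         contrast_gain = 1, vignette_strength = 0,
                         noise_sigma = 0) {
  tone_curve <- as.numeric(tone_curve)
  if (length(tone_curve) != 256 || any(diff(tone_curve) < 0))
    stop_param("tone_curve must be a monotone non-decreasing 256-vector")
  structure(list(name = name, tone_curve = tone_curve,
                 base_intensity = base_intensity,
                 contrast_gain = contrast_gain,
                 vignette_strength = vignette_strength,
                 noise_sigma = noise_sigma),
            class = "device_style")
}

#' @describeIn device_style bright, higher-contrast style playing the role
#'   of the internal (training) device.
#' @export
style_internal <- function() {
  v <- 0:255 / 255
  # gentle S-curve brightening midtones
  tc <- 255 * (v + 0.25 * sin(pi * v) * v * (1 - v) * 4)
  tc <- cummax(pmin(pmax(tc, 0), 255))
  device_style("internal", tone_curve = tc, base_intensity = 10,
               contrast_gain = 1.15, vignette_strength = 0.15,
               noise_sigma = 3)
}

#' @describeIn device_style darker, gamma-compressed style playing the role
#'   of the external (deployment) device, with a strong histogram gap from
#'   [style_internal()].
#' @export
style_external <- function() {
  v <- 0:255 / 255
  tc <- 255 * v^1.8 * 0.75
  tc <- cummax(pmin(pmax(tc, 0), 255))
  device_style("external", tone_curve = tc, base_intensity = 4,
               contrast_gain = 0.85, vignette_strength = 0.45,
               noise_sigma = 5)
}

# Geometry of the phantom: returns the label mask {0,1,2} and the ideal
# (pre-style) intensity rendering.
phantom_geometry <- function(spec) {
  h <- spec$height; w <- spec$width
  x <- matrix(rep(seq_len(w), each = h), h, w)   # column index
  y <- matrix(rep(seq_len(h), times = w), h, w)  # row index
  u <- (2 * x / w) - 1                           # -1..1 across width
  curv <- spec$eyelid_curvature
  ytop <- h * (0.16 + curv * u^2)
  ybot <- h * (0.84 - curv * u^2)
  band <- y >= ytop & y <= ybot

  # Parallel wavy stripes realised as a periodic tiling: all glands share
  # one tortuosity offset, so stripes never overlap and the gland fraction
  # of the band equals gland_width_frac up to pixel discretization.
  spacing <- w / spec$n_glands
  amp <- stats::runif(1, 0.1, 0.25) * spacing
  phase <- stats::runif(1, 0, 2 * pi)
  period <- stats::runif(1, 0.8, 1.4) * h
  off <- amp * sin(2 * pi * seq_len(h) / period + phase)   # per row

  xs <- sweep(x, 1, off) / spacing          # stripe coordinate
  frac <- xs - floor(xs)                    # position within one period
  gid <- (floor(xs) %% spec$n_glands) + 1   # gland index per pixel
  in_stripe <- abs(frac - 0.5) <= spec$gland_width_frac / 2

  # Per-gland keep fraction realising proximal truncation of the distal
  # end. Calibrated against the realized (rasterized) full-stripe coverage
  # so the mask's loss rate tracks atrophy_frac despite pixel quantization.
  cover <- sum(in_stripe & band) / max(sum(band), 1)
  k_global <- (1 - spec$atrophy_frac) / max(cover, 1e-9)
  keep <- pmin(1, pmax(0, k_global + stats::runif(spec$n_glands, -0.04, 0.04)))
  if (spec$atrophy_frac >= 1) keep[] <- -1  # complete dropout: no MG pixels

  depth <- (y - ytop) / pmax(ybot - ytop, 1)     # 0 proximal .. 1 distal
  gland <- in_stripe & band & depth <= matrix(keep[gid], h, w)
  mask <- matrix(0L, h, w)
  mask[band] <- 1L
  mask[gland] <- 2L

  # ideal intensities: dark background, mid lid, bright glands
  img <- matrix(35, h, w)
  img[band] <- 110
  img[gland] <- 185
  # mild longitudinal shading inside glands for texture
  img[gland] <- img[gland] - 25 * depth[gland]
  list(mask = mask, ideal = img)
}

apply_style <- function(img, style) {
  h <- nrow(img); w <- ncol(img)
  out <- style$contrast_gain * (img - 128) + 128 + style$base_intensity
  out <- style$tone_curve[clamp8(out) + 1L]
  if (style$vignette_strength > 0) {
    ry <- (seq_len(h) - (h + 1) / 2) / (h / 2)
    rx <- (seq_len(w) - (w + 1) / 2) / (w / 2)
    r2 <- outer(ry^2, rx^2, `+`)
    out <- out * (1 - style$vignette_strength * pmin(r2 / 2, 1))
  }
  if (style$noise_sigma > 0)
    out <- out + stats::rnorm(length(out), 0, style$noise_sigma)
  matrix(clamp8(out), h, w)
}

#' Generate one labelled phantom
#'
#' Renders the gland/eyelid geometry of `spec`, applies the device `style`
#' to the intensities, and returns the 8-bit image together with its
#' ground-truth label mask (0 background, 1 eyelid, 2 MG).
#'
#' @param spec a [phantom_spec()].
#' @param style a [device_style()].
#' @return an object of class `labeled_image`: list with `image` (8-bit
#'   matrix), `mask` (labels 0/1/2), `style_name`, and `true_loss_rate`
#'   (the mask's realised MG loss rate).
#' @examples
#' ph <- generate_phantom(phantom_spec(atrophy_frac = 0.4, seed = 7),
#'                        style_internal())
#' mg_loss_rate(ph$mask)
#' @export
generate_phantom <- function(spec, style) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(style, "device_style"))
  with_seed(spec$seed, {
    geo <- phantom_geometry(spec)
    img <- apply_style(geo$ideal, style)
    structure(list(image = img, mask = geo$mask, style_name = style$name,
                   true_loss_rate = mg_loss_rate(geo$mask),
                   seed = spec$seed),
              class = "labeled_image")
  })
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %dx%d, style '%s', MG loss rate %.3f\n",
              nrow(x$image), ncol(x$image), x$style_name, x$true_loss_rate))
  invisible(x)
}

#' Sampler over phantom specifications
#'
#' Returns a function mapping a seed to a random [phantom_spec()], used by
#' [generate_dataset()]. Atrophy is drawn uniformly over `atrophy_range`;
#' gland count over `n_glands_range`.
#'
#' @param height,width image dimensions passed through to every spec.
#' @param atrophy_range,n_glands_range sampling ranges.
#' @param noise_sigma noise level passed through.
#' @return `function(seed) -> phantom_spec`.
#' @export
phantom_sampler <- function(height = 256, width = 256,
                            atrophy_range = c(0, 0.8),
                            n_glands_range = c(8, 16),
                            noise_sigma = 6) {
  force(height); force(width); force(atrophy_range); force(n_glands_range)
  function(seed) {
    with_seed(seed, {
      phantom_spec(height = height, width = width,
                   n_glands = sample(n_glands_range[1]:n_glands_range[2], 1),
                   atrophy_frac = stats::runif(1, atrophy_range[1],
                                               atrophy_range[2]),
                   eyelid_curvature = stats::runif(1, 0.05, 0.18),
                   noise_sigma = noise_sigma,
                   seed = derive_seed(seed, 1L))
    })
  }
}

#' Generate a dataset of labelled phantoms
#'
#' Per-image seeds are derived deterministically from the master seed by a
#' counter hash, so the collection is reproducible independent of
#' generation order.
#'
#' @param n number of images (>= 1).
#' @param spec_sampler a `function(seed) -> phantom_spec`, e.g.
#'   [phantom_sampler()].
#' @param style a [device_style()].
#' @param seed master integer seed.
#' @return list of `labeled_image` objects, length `n`.
#' @export
generate_dataset <- function(n, spec_sampler = phantom_sampler(),
                             style = style_internal(), seed = 1L) {
  if (n < 1) stop_param("n must be >= 1")
  lapply(seq_len(n), function(i) {
    sp <- spec_sampler(derive_seed(seed, i))
    generate_phantom(sp, style)
  })
}

#' Histogram gap between two image populations
#'
#' Total-variation style distance between the average normalized 256-bin
#' histograms of two image sets: the sum of absolute bin differences, in
#' \[0, 2\]. 0 means identical average histograms; 2 means disjoint support.
#'
#' @param setA,setB lists of `labeled_image` objects or 8-bit matrices.
#' @return a scalar in \[0,2\].
#' @export
style_histogram_gap <- function(setA, setB) {
  ha <- average_histogram(setA)
  hb <- average_histogram(setB)
  sum(abs(ha$bins - hb$bins))
}
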