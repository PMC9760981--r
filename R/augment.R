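# Training-set augmentation: gamma transformation, rotation, blur, noise
# addition and image flips, applied consistently to image and mask. The
# recipe expands every training pair exactly 12-fold, with geometric
# transforms shared by image and mask (nearest-neighbour for labels) and
# photometric transforms applied to the image only.

#' Augmentation configuration
#'
#' The default recipe produces one augmented pair per entry: 2 flips +
#' 3 rotations + 3 gamma curves + 2 Gaussian blurs + 2 noise draws =
#' exactly 12 variants per input, an auditable realisation of a 12-fold
#' expansion. Any configuration whose recipe size differs from 12 is
#' rejected, since the expansion factor is a fixed contract of the
#' training protocol.
#'
#' @param gamma_values gamma exponents (> 0), photometric.
#' @param rotation_degrees rotation angles; borders exposed by rotation are
#'   filled with background (label 0, intensity 0).
#' @param blur_sigmas Gaussian blur standard deviations, pixels.
#' @param noise_sigmas additive noise standard deviations, 8-bit units.
#' @param flips subset of `c("horizontal", "vertical")`.
#' @param seed RNG seed for the noise draws.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(gamma_values = c(0.7, 1.3, 1.6),
                           rotation_degrees = c(-10, 10, 180),
                           blur_sigmas = c(1, 2),
                           noise_sigmas = c(5, 10),
                           flips = c("horizontal", "vertical"),
                           seed = 1L) {
  if (!all(gamma_values > 0)) stop_param("gamma values must be > 0")
  if (!all(flips %in% c("horizontal", "vertical")))
    stop_param("flips must be a subset of {horizontal, vertical}")
  n <- length(gamma_values) + length(rotation_degrees) +
       length(blur_sigmas) + length(noise_sigmas) + length(flips)
  if (n != 12)
    stop_param(paste("augmentation recipe yields %d variants per image;",
                     "the training protocol requires exactly 12"), n)
  structure(list(gamma_values = gamma_values,
                 rotation_degrees = rotation_degrees,
                 blur_sigmas = blur_sigmas, noise_sigmas = noise_sigmas,
                 flips = flips, seed = as.integer(seed)),
            class = "augment_config")
}

flip_matrix <- function(m, dir) {
  if (dir == "horizontal") m[, rev(seq_len(ncol(m))), drop = FALSE]
  else m[rev(seq_len(nrow(m))), , drop = FALSE]
}

rotate_pair <- function(img, mask, angle) {
  if (angle %% 360 == 0) return(list(img = img, mask = mask))
  if (angle %% 360 == 180) {
    # exact pixel permutation; no resampling
    return(list(img = img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img)))],
                mask = mask[rev(seq_len(nrow(mask))), rev(seq_len(ncol(mask)))]))
  }
  od <- dim(img)
  ri <- EBImage::rotate(img, angle, filter = "bilinear",
                        output.dim = od, bg.col = 0)
  rm_ <- EBImage::rotate(mask + 0, angle, filter = "none",
                         output.dim = od, bg.col = 0)
  list(img = matrix(clamp8(as.numeric(ri)), od[1], od[2]),
       mask = matrix(as.integer(round(as.numeric(rm_))), od[1], od[2]))
}

#' Augment one labelled pair
#'
#' @param item a `labeled_image` (see [generate_phantom()]) or a list with
#'   `image` and `mask`.
#' @param config an [augment_config()].
#' @return list of exactly 12 `labeled_image` objects. Masks stay over
#'   \{0,1,2\}; image and mask dimensions always match.
#' @export
augment_pair <- function(item, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  img <- item$image; mask <- item$mask
  check_uint8(img); check_mask(mask)
  out <- list()
  keep <- function(im, mk) {
    structure(list(image = im, mask = mk,
                   style_name = item$style_name %||% NA_character_,
                   true_loss_rate = item$true_loss_rate %||% NA_real_),
              class = "labeled_image")
  }
  for (f in config$flips)
    out[[length(out) + 1]] <- keep(flip_matrix(img, f), flip_matrix(mask, f))
  for (a in config$rotation_degrees) {
    r <- rotate_pair(img, mask, a)
    out[[length(out) + 1]] <- keep(r$img, r$mask)
  }
  for (g in config$gamma_values)
    out[[length(out) + 1]] <- keep(matrix(clamp8(255 * (img / 255)^g),
                                          nrow(img), ncol(img)), mask)
  for (s in config$blur_sigmas) {
    b <- EBImage::gblur(img, sigma = s)
    out[[length(out) + 1]] <- keep(matrix(clamp8(as.numeric(b)),
                                          nrow(img), ncol(img)), mask)
  }
  with_seed(config$seed, {
    for (s in config$noise_sigmas) {
      n <- img + stats::rnorm(length(img), 0, s)
      out[[length(out) + 1]] <- keep(matrix(clamp8(n), nrow(img), ncol(img)),
                                     mask)
    }
  })
  out
}

#' Expand a dataset with the augmentation recipe
#'
#' @param dataset list of `labeled_image` objects.
#' @param config an [augment_config()]; per-item noise seeds are derived
#'   from `config$seed`.
#' @param keep_original prepend the unaugmented pairs (default `TRUE`).
#' @return list of `labeled_image` objects.
#' @export
augment_dataset <- function(dataset, config = augment_config(),
                            keep_original = TRUE) {
  out <- if (keep_original) dataset else list()
  for (i in seq_along(dataset)) {
    ci <- config
    ci$seed <- derive_seed(config$seed, i)
    out <- c(out, augment_pair(dataset[[i]], ci))
  }
  out
}
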