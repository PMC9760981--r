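# File formats: paired PNG image/mask files with a CSV manifest, and the
# histogram template as a 256-line CSV of bin masses.

luma_weights <- c(0.299, 0.587, 0.114)

png_to_uint8 <- function(arr, info = NULL) {
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3)
      arr[, , 1] * luma_weights[1] + arr[, , 2] * luma_weights[2] +
        arr[, , 3] * luma_weights[3]
    else arr[, , 1]
  }
  if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8) {
    warning(sprintf("%d-bit image rescaled to 8 bits", info$bit.depth),
            call. = FALSE)
  }
  matrix(clamp8(arr * 255), nrow(arr), ncol(arr))
}

#' Write one labelled pair as PNG files
#'
#' Produces `<id>_img.png` and `<id>_mask.png`; the mask file stores the
#' labels literally as byte values 0, 1, 2.
#'
#' @param item a `labeled_image`.
#' @param dir output directory (created if needed).
#' @param id file stem.
#' @return invisibly, the two paths.
#' @export
write_labeled_image <- function(item, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ip <- file.path(dir, paste0(id, "_img.png"))
  mp <- file.path(dir, paste0(id, "_mask.png"))
  png::writePNG(item$image / 255, ip)
  png::writePNG(item$mask / 255, mp)
  invisible(c(ip, mp))
}

#' Read and validate a labelled image/mask pair
#'
#' @param img_path path to the grayscale image PNG (color images are
#'   converted with luma weights; 16-bit images are rescaled to 8 bits
#'   with a warning).
#' @param mask_path path to the mask PNG, byte values in \{0,1,2\}.
#' @return a `labeled_image`.
#' @export
read_labeled_pair <- function(img_path, mask_path) {
  ia <- png::readPNG(img_path, info = TRUE)
  img <- png_to_uint8(ia, attr(ia, "info"))
  ma <- png::readPNG(mask_path)
  if (length(dim(ma)) == 3) ma <- ma[, , 1]
  mask <- matrix(as.integer(round(ma * 255)), nrow(ma), ncol(ma))
  bad <- setdiff(unique(as.vector(mask)), c(0L, 1L, 2L))
  if (length(bad))
    stop_param("mask contains labels outside {0,1,2}: %s",
               paste(bad, collapse = ", "))
  if (!all(dim(img) == dim(mask)))
    stop_param("image (%dx%d) and mask (%dx%d) dimensions differ",
               nrow(img), ncol(img), nrow(mask), ncol(mask))
  structure(list(image = img, mask = mask, style_name = NA_character_,
                 true_loss_rate = mg_loss_rate(mask), seed = NA_integer_),
            class = "labeled_image")
}

#' Write a dataset as paired PNGs with a CSV manifest
#'
#' @param dataset list of `labeled_image` objects.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("im%04d", seq_along(dataset))
  for (i in seq_along(dataset))
    write_labeled_image(dataset[[i]], dir, ids[i])
  manifest <- data.frame(
    id = ids,
    style = vapply(dataset, function(x) x$style_name %||% NA_character_,
                   character(1)),
    true_loss_rate = vapply(dataset, function(x) x$true_loss_rate,
                            numeric(1)),
    seed = vapply(dataset, function(x) as.integer(x$seed %||% NA), integer(1)))
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of `labeled_image` objects.
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    it <- read_labeled_pair(
      file.path(dir, paste0(manifest$id[i], "_img.png")),
      file.path(dir, paste0(manifest$id[i], "_mask.png")))
    it$style_name <- manifest$style[i]
    it$seed <- manifest$seed[i]
    it
  })
}

#' Persist / load a histogram template as a 256-line CSV
#' @param template a `histogram_template`.
#' @param path CSV path.
#' @return `read_template` returns a `histogram_template`.
#' @export
write_template <- function(template, path) {
  write.csv(data.frame(level = 0:255, mass = template$bins), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  df <- read.csv(path)
  histogram_template(df$mass, source_set = path)
}
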