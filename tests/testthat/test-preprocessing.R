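test_that("average histogram equals the brute-force per-bin mean", {
  imgs <- lapply(tiny_set(8, seed = 11), `[[`, "image")
  tpl <- average_histogram(imgs)
  manual <- Reduce(`+`, lapply(imgs, function(im) {
    h <- oracle_hist256(im); h / sum(h)
  })) / length(imgs)
  expect_equal(tpl$bins, manual, tolerance = 1e-12)
  expect_equal(sum(tpl$bins), 1, tolerance = 1e-9)
})

test_that("average histogram of identical images is the single histogram, and
           of two constant images splits the mass", {
  im <- tiny_phantom(2)$image
  tpl <- average_histogram(list(im, im, im))
  expect_equal(tpl$bins, hist256(im) / length(im), tolerance = 1e-12)
  tpl2 <- average_histogram(list(matrix(0L, 8, 8), matrix(255L, 8, 8)))
  expect_equal(tpl2$bins[c(1, 256)], c(0.5, 0.5))
  expect_equal(sum(tpl2$bins[2:255]), 0)
})

test_that("average histogram is permutation invariant and rejects bad input", {
  imgs <- lapply(tiny_set(5, seed = 12), `[[`, "image")
  expect_equal(average_histogram(imgs)$bins,
               average_histogram(rev(imgs))$bins)
  expect_error(average_histogram(list()), "empty")
  expect_error(average_histogram(list(matrix(0.5, 4, 4))), "8-bit")
})

test_that("self-specification is identity up to one gray level", {
  for (s in 1:5) {
    img <- tiny_phantom(s)$image
    tpl <- average_histogram(list(img))
    out <- specify_histogram(img, tpl)
    expect_lte(max(abs(out$image - img)), 1)
  }
})

test_that("a degenerate single-level template collapses the image to it", {
  bins <- numeric(256); bins[129] <- 1   # all mass at level 128
  out <- specify_histogram(tiny_phantom(3)$image, histogram_template(bins))
  expect_true(all(out$image == 128))
})

test_that("the HS look-up table matches an exhaustive CDF-inversion oracle", {
  # 4-level toy image at frequencies 0.4/0.3/0.2/0.1 specified to uniform
  v <- rep(c(0L, 64L, 128L, 192L), times = c(40, 30, 20, 10))
  img <- matrix(v, 10, 10)
  tpl <- histogram_template(rep(1, 256))
  lut <- specify_histogram(img, tpl)$lut
  icdf <- cumsum(oracle_hist256(img)) / 100
  tcdf <- cumsum(rep(1 / 256, 256))
  oracle_lut <- vapply(1:256, function(i) {
    (which(tcdf >= icdf[i] - 1e-12)[1]) - 1L
  }, integer(1))
  expect_identical(lut, oracle_lut)
  expect_true(all(diff(lut) >= 0))
})

test_that("specification is order preserving and matches the template CDF
           within the quantization bound", {
  set.seed(13)
  pool <- tiny_set(10, seed = 14, style = style_internal())
  tpl <- average_histogram(pool)
  tcdf <- cumsum(tpl$bins)
  bound <- max(tpl$bins)
  for (s in 1:10) {
    img <- tiny_phantom(s, style = style_external())$image
    out <- specify_histogram(img, tpl)
    expect_true(all(diff(out$lut) >= 0))
    ocdf <- cumsum(hist256(out$image)) / length(out$image)
    expect_lte(max(abs(ocdf - tcdf)), bound + 1e-9)
  }
})

test_that("single-tile CLAHE without clipping equals global equalization", {
  img <- tiny_phantom(7, size = 64)$image
  out <- clahe(img, clahe_params(tile_size = 64, clip_limit = 1e6))
  expect_equal(out, oracle_global_he(img))
})

test_that("CLAHE preserves dimensions and range; constant input is identity", {
  img <- tiny_phantom(8, size = 96)$image
  out <- clahe(img, clahe_params(tile_size = 24))
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))
  flat <- matrix(37L, 64, 64)
  expect_identical(clahe(flat, clahe_params(tile_size = 16)), flat)
  expect_error(clahe(img, clahe_params(tile_size = 128)), "exceeds")
  expect_error(clahe_params(tile_size = 4), "tile_size")
  expect_error(clahe_params(clip_limit = 0), "clip_limit")
})

test_that("templates survive a CSV round trip", {
  tpl <- average_histogram(tiny_set(3, seed = 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_template(tpl, path)
  back <- read_template(path)
  expect_equal(back$bins, tpl$bins, tolerance = 1e-12)
})
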