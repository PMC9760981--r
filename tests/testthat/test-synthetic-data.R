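test_that("phantom masks are valid label images tracking the atrophy target", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1)
    hh <- sample(c(64, 96, 128), 1)
    ph <- generate_phantom(
      phantom_spec(height = hh, width = hh, atrophy_frac = a,
                   n_glands = sample(8:16, 1), seed = i),
      if (i %% 2) style_external() else style_internal())
    expect_true(all(ph$mask %in% 0:2))
    expect_true(all(ph$image >= 0 & ph$image <= 255))
    expect_identical(dim(ph$image), dim(ph$mask))
    expect_lt(abs(mg_loss_rate(ph$mask) - a), 0.05)
  }
})

test_that("atrophy extremes give the expected loss rates", {
  none <- generate_phantom(phantom_spec(atrophy_frac = 0, seed = 2),
                           style_internal())
  expect_lte(mg_loss_rate(none$mask), 0.05)
  all_gone <- generate_phantom(phantom_spec(atrophy_frac = 1, seed = 2),
                               style_internal())
  expect_identical(sum(all_gone$mask == 2), 0L)
  expect_equal(mg_loss_rate(all_gone$mask), 1)
})

test_that("generation is deterministic for a fixed seed", {
  p1 <- generate_phantom(phantom_spec(seed = 9), style_external())
  p2 <- generate_phantom(phantom_spec(seed = 9), style_external())
  expect_identical(p1, p2)
  d1 <- tiny_set(4, seed = 5)
  d2 <- tiny_set(4, seed = 5)
  expect_identical(d1, d2)
})

test_that("gland pixels are brighter than surrounding eyelid before noise", {
  sp <- phantom_spec(noise_sigma = 0, seed = 3)
  ph <- generate_phantom(sp, device_style("flat"))  # identity tone curve
  expect_gt(mean(ph$image[ph$mask == 2]), mean(ph$image[ph$mask == 1]))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_spec(height = 32), "at least 64")
  expect_error(phantom_spec(atrophy_frac = 1.2), "atrophy_frac")
  expect_error(phantom_spec(n_glands = 0), "n_glands")
  expect_error(generate_dataset(0), "n must be")
  expect_error(device_style("bad", tone_curve = 255:0), "monotone")
})

test_that("two device styles share geometry but differ in histograms", {
  spec <- phantom_spec(height = 96, width = 96, atrophy_frac = 0.4, seed = 6)
  a <- generate_phantom(spec, style_internal())
  b <- generate_phantom(spec, style_external())
  expect_identical(a$mask, b$mask)
  expect_gt(style_histogram_gap(list(a), list(b)), 0)
})

test_that("style populations differ in mean intensity beyond sampling error", {
  a <- tiny_set(25, seed = 7, style = style_internal())
  b <- tiny_set(25, seed = 7, style = style_external())
  ma <- vapply(a, function(x) mean(x$image), numeric(1))
  mb <- vapply(b, function(x) mean(x$image), numeric(1))
  pooled_se <- sqrt(var(ma) / 25 + var(mb) / 25)
  expect_gt(abs(mean(ma) - mean(mb)), 2 * pooled_se)
})

test_that("histogram gap matches a per-bin summation oracle and its bounds", {
  a <- tiny_set(10, seed = 8, style = style_internal())
  b <- tiny_set(10, seed = 9, style = style_external())
  ha <- Reduce(`+`, lapply(a, function(x) {
    h <- oracle_hist256(x$image); h / sum(h)
  })) / 10
  hb <- Reduce(`+`, lapply(b, function(x) {
    h <- oracle_hist256(x$image); h / sum(h)
  })) / 10
  expect_equal(style_histogram_gap(a, b), sum(abs(ha - hb)), tolerance = 1e-12)
  expect_equal(style_histogram_gap(a, a), 0)
  # disjoint single-bin histograms sit at the upper bound 2
  c10 <- list(matrix(10, 16, 16)); c200 <- list(matrix(200, 16, 16))
  expect_equal(style_histogram_gap(c10, c200), 2)
})

test_that("PNG round trip preserves images, masks and manifest", {
  d <- tiny_set(3, seed = 4)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  back <- read_dataset(dir)
  for (i in 1:3) {
    expect_identical(back[[i]]$image, d[[i]]$image)
    expect_identical(back[[i]]$mask, d[[i]]$mask)
  }
  mf <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(mf$true_loss_rate,
               vapply(d, function(x) x$true_loss_rate, numeric(1)))
})

test_that("invalid masks are rejected on read with the offending values named", {
  dir <- withr::local_tempdir()
  img <- matrix(100L, 32, 32)
  png::writePNG(img / 255, file.path(dir, "a_img.png"))
  bad <- matrix(0L, 32, 32); bad[1, 1] <- 3L
  png::writePNG(bad / 255, file.path(dir, "a_mask.png"))
  expect_error(read_labeled_pair(file.path(dir, "a_img.png"),
                                 file.path(dir, "a_mask.png")),
               "outside \\{0,1,2\\}.*3")
})
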