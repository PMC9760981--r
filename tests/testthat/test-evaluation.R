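test_that("region metrics match a per-pixel counting oracle", {
  # fixed arithmetic case: |P|=6, |T|=4, overlap 3
  pred <- matrix(0L, 8, 8); pred[1:6] <- 2L
  truth <- matrix(0L, 8, 8); truth[4:7] <- 2L
  m <- region_metrics(pred, truth, 2)
  expect_equal(m$dsc, 0.6)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.5)
  set.seed(31)
  for (i in 1:40) {
    p <- matrix(sample(0:2, 100, TRUE), 10, 10)
    t <- matrix(sample(0:2, 100, TRUE), 10, 10)
    for (r in 1:2) {
      m <- region_metrics(p, t, r)
      o <- oracle_region_metrics(p, t, r)
      expect_equal(m$dsc, o[["dsc"]], tolerance = 1e-9)
      expect_equal(m$recall, o[["recall"]], tolerance = 1e-9)
      expect_equal(m$precision, o[["precision"]], tolerance = 1e-9)
    }
  }
})

test_that("metric identities and edge cases hold", {
  p <- matrix(sample(0:2, 64, TRUE), 8, 8)
  m <- region_metrics(p, p, 2)
  expect_equal(c(m$dsc, m$recall, m$precision), c(1, 1, 1))
  # disjoint non-empty regions
  a <- matrix(0L, 4, 4); a[1:4] <- 2L
  b <- matrix(0L, 4, 4); b[9:12] <- 2L
  m2 <- region_metrics(a, b, 2)
  expect_equal(c(m2$dsc, m2$recall, m2$precision), c(0, 0, 0))
  # DSC is the harmonic mean of precision and recall when both positive
  set.seed(32)
  for (i in 1:20) {
    p <- matrix(sample(0:2, 100, TRUE), 10, 10)
    t <- matrix(sample(0:2, 100, TRUE), 10, 10)
    m <- region_metrics(p, t, 1)
    if (isTRUE(m$precision > 0) && isTRUE(m$recall > 0))
      expect_equal(m$dsc,
                   2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-9)
  }
  # empty truth region flags the record
  expect_true(region_metrics(a, matrix(0L, 4, 4), 2)$flagged)
  expect_error(region_metrics(a, matrix(0L, 5, 5), 2), "dimensions")
})

test_that("MG loss rate counts areas exactly and is flip invariant", {
  m <- matrix(0L, 10, 10)
  m[1:80] <- 2L; m[61:80] <- 1L   # 80 lid pixels, 60 gland
  expect_equal(mg_loss_rate(m), 0.25)
  expect_equal(mg_loss_rate(m), oracle_loss_rate(m), tolerance = 1e-12)
  expect_equal(mg_loss_rate(m[, 10:1]), 0.25)
  expect_equal(mg_loss_rate(m[10:1, ]), 0.25)
  only_lid <- matrix(c(0L, 1L), 4, 4)
  expect_equal(mg_loss_rate(only_lid), 1)
  all_gland <- matrix(2L, 4, 4)
  expect_equal(mg_loss_rate(all_gland), 0)
  expect_error(mg_loss_rate(matrix(0L, 4, 4)), "undefined")
})

test_that("meiboscore grades in one-third increments", {
  expect_identical(meiboscore(0), 0L)
  expect_identical(meiboscore(0.2), 1L)
  expect_identical(meiboscore(1 / 3), 1L)
  expect_identical(meiboscore(0.5), 2L)
  expect_identical(meiboscore(2 / 3), 2L)
  expect_identical(meiboscore(0.9), 3L)
  expect_identical(meiboscore(1), 3L)
  expect_error(meiboscore(1.1), "rate")
  # non-decreasing, 4 grades, interior transitions spaced by 1/3
  r <- seq(0, 1, by = 1e-4)
  g <- meiboscore(r)
  expect_true(all(diff(g) >= 0))
  expect_identical(sort(unique(g)), 0:3)
  trans <- r[which(diff(g) == 1) + 1]
  expect_equal(diff(trans), rep(1 / 3, 2), tolerance = 1e-3)
})

test_that("loss-rate RMSE matches direct arithmetic and scales linearly", {
  expect_equal(loss_rate_rmse(predicted = c(0.2, 0.5), true = c(0.1, 0.5)),
               sqrt(0.01 / 2))
  expect_equal(loss_rate_rmse(predicted = c(0.3, 0.3), true = c(0.3, 0.3)), 0)
  set.seed(33)
  p <- runif(1000); t <- runif(1000)
  brute <- sqrt(sum((p - t)^2) / 1000)
  expect_equal(loss_rate_rmse(predicted = p, true = t), brute,
               tolerance = 1e-12)
  expect_equal(loss_rate_rmse(predicted = t + 2 * (p - t), true = t),
               2 * loss_rate_rmse(predicted = p, true = t),
               tolerance = 1e-12)
  df <- data.frame(predicted_rate = p, true_rate = t)
  expect_equal(loss_rate_rmse(df), brute, tolerance = 1e-12)
  expect_error(loss_rate_rmse(predicted = numeric()), "records")
})

test_that("Mann-Whitney p-values agree with exact enumeration for all
           small tie-free samples", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    a <- round(runif(n), 6); b <- round(runif(m) + 0.1 * (i %% 3), 6)
    got <- compare_groups(a, b)
    want <- oracle_mwu_exact(a, b)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
    expect_equal(got$U, want$U)
    expect_identical(got$significant, got$p_value < 0.01)
  }
})

test_that("identical samples are never declared different and complete
           separation gives U = 0 for one orientation", {
  x <- c(0.61, 0.72, 0.55, 0.68)
  r <- compare_groups(x, x)
  expect_gt(r$p_value, 0.9)
  expect_false(r$significant)
  sep <- compare_groups(c(101, 102, 103), c(1, 2, 3))
  expect_equal(unname(sep$U), 9)   # mirrored orientation has U = 0
  expect_equal(unname(compare_groups(c(1, 2, 3), c(101, 102, 103))$U), 0)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("the embedding separates distinct styles and not a null split", {
  a <- tiny_set(15, seed = 41, style = style_internal())
  b <- tiny_set(15, seed = 42, style = style_external())
  emb <- domain_embedding(a, b, seed = 1)
  expect_equal(nrow(emb$coords), 30)
  expect_gt(emb$separation, 0)
  # random split of one homogeneous set: separation near zero
  pool <- tiny_set(30, seed = 43, style = style_internal())
  null_emb <- domain_embedding(pool[1:15], pool[16:30], seed = 2)
  expect_lt(abs(null_emb$separation), 0.2)
  expect_error(domain_embedding(pool[1:2], pool[3:4], seed = 1), "at least 5")
})
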