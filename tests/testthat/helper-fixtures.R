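# Shared fixtures. Everything is generated in code; small sizes keep the
# default test run fast.

tiny_phantom <- function(seed = 1, atrophy = 0.3, size = 64,
                         style = style_internal()) {
  generate_phantom(phantom_spec(height = size, width = size,
                                atrophy_frac = atrophy, seed = seed),
                   style)
}

tiny_set <- function(n, seed = 1, size = 64, style = style_internal(),
                     atrophy_range = c(0, 0.8)) {
  generate_dataset(n, phantom_sampler(height = size, width = size,
                                      atrophy_range = atrophy_range),
                   style, seed = seed)
}

# independent brute-force oracles -------------------------------------------

oracle_hist256 <- function(img) {
  counts <- numeric(256)
  for (v in as.vector(img)) counts[v + 1] <- counts[v + 1] + 1
  counts
}

oracle_region_metrics <- function(pred, truth, label) {
  ni <- np <- nt <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == label; t <- truth[i] == label
    np <- np + p; nt <- nt + t; ni <- ni + (p && t)
  }
  c(dsc = 2 * ni / (np + nt), recall = ni / nt, precision = ni / np)
}

oracle_loss_rate <- function(mask) {
  1 - sum(mask == 2) / sum(mask %in% c(1, 2))
}

oracle_dice_loss <- function(p, mask, smooth = 1e-6) {
  acc <- 0
  for (c in 1:3) {
    pc <- p[, , c]; tc <- (mask == c - 1) * 1
    acc <- acc + (2 * sum(pc * tc) + smooth) / (sum(pc) + sum(tc) + smooth)
  }
  1 - acc / 3
}

# exact two-sided Mann-Whitney p-value by enumerating all group assignments
oracle_mwu_exact <- function(a, b) {
  pool <- c(a, b); n <- length(a); m <- length(b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# global histogram equalization, the single-tile CLAHE limit
oracle_global_he <- function(img) {
  counts <- oracle_hist256(img)
  map <- round(255 * cumsum(counts) / length(img))
  matrix(map[img + 1], nrow(img), ncol(img))
}
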