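# Domain-gap diagnostic: nonlinear 2-D embedding of two image populations
# plus a silhouette-based separation score. A wide gap between the device
# clusters on the embedding indicates a distribution shift the network
# will feel at deployment.

#' 2-D embedding of two image sets with a separation score
#'
#' Images are downscaled to `feature_size` x `feature_size`, flattened,
#' reduced by PCA, and embedded in 2-D with nonmetric multidimensional
#' scaling (a nonlinear, rank-preserving neighbour embedding). The
#' separation score is the mean silhouette width of the two set labels on
#' the embedding, in \[-1, 1\]: values near 0 mean the populations are
#' intermixed; clearly positive values mean a visible domain gap.
#'
#' @param setA,setB lists of `labeled_image` objects or 8-bit matrices.
#' @param seed RNG seed (tie-breaking jitter on duplicate feature
#'   vectors).
#' @param feature_size side length of the downscaled feature image
#'   (default 32; set to the full resolution to embed raw pixels).
#' @param n_pcs number of principal components kept before the embedding.
#' @return list with `coords` (data frame: x, y, set) and `separation`
#'   (mean silhouette width).
#' @export
domain_embedding <- function(setA, setB, seed = 1L, feature_size = 32L,
                             n_pcs = 30L) {
  A <- as_image_list(setA); B <- as_image_list(setB)
  n <- length(A) + length(B)
  if (n < 5) stop_param("need at least 5 images in total (got %d)", n)
  feats <- t(vapply(c(A, B), function(im)
    as.numeric(resize_image(im, feature_size, feature_size, "bilinear")),
    numeric(feature_size^2)))
  feats <- feats / 255
  labels <- rep(1:2, c(length(A), length(B)))
  k <- min(n_pcs, n - 1, ncol(feats))
  pc <- stats::prcomp(feats, rank. = k)$x
  with_seed(seed, {
    d <- stats::dist(pc)
    if (any(d < 1e-9)) d <- d + stats::runif(length(d), 1e-9, 1e-6)
    emb <- MASS::isoMDS(d, k = 2, trace = FALSE)$points
  })
  sil <- cluster::silhouette(labels, stats::dist(emb))
  list(coords = data.frame(x = emb[, 1], y = emb[, 2],
                           set = factor(labels, labels = c("A", "B"))),
       separation = mean(sil[, "sil_width"]))
}
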