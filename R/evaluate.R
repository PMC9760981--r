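# Evaluation: per-region segmentation metrics (DSC, recall, precision),
# MG loss rate and meiboscore grading, loss-rate RMSE, and Mann-Whitney
# group comparisons.

#' Per-region segmentation metrics
#'
#' Both masks are binarized at `region_label`; then
#' `DSC = 2|P∩T| / (|P|+|T|)`, `recall = |P∩T|/|T|`,
#' `precision = |P∩T|/|P|`. If the truth region is empty, recall is
#' undefined: the record is returned with `flagged = TRUE` and should be
#' excluded from aggregates.
#'
#' @param pred,truth label matrices over \{0,1,2\} with equal dimensions.
#' @param region_label 1 (eyelid) or 2 (MG).
#' @param image_id optional identifier carried through.
#' @return list with `dsc`, `recall`, `precision`, `region`, `flagged`.
#' @export
region_metrics <- function(pred, truth, region_label, image_id = NA) {
  if (!all(dim(pred) == dim(truth)))
    stop_param("pred and truth dimensions differ")
  if (!region_label %in% c(1, 2)) stop_param("region_label must be 1 or 2")
  P <- pred == region_label; T_ <- truth == region_label
  np <- sum(P); nt <- sum(T_); ni <- sum(P & T_)
  flagged <- nt == 0
  list(image_id = image_id,
       region = if (region_label == 2) "MG" else "eyelid",
       dsc = if (np + nt > 0) 2 * ni / (np + nt) else NA_real_,
       recall = if (nt > 0) ni / nt else NA_real_,
       precision = if (np > 0) ni / np else NA_real_,
       flagged = flagged)
}

#' Meibomian-gland loss rate
#'
#' The fraction of the eyelid area lacking visible glands:
#' `1 - MG area / eyelid area`, where the eyelid area is the union of
#' labels 1 and 2 (glands lie within the eyelid, so the union keeps the
#' rate inside \[0,1\]).
#'
#' @param mask label matrix over \{0,1,2\}.
#' @return scalar in \[0,1\].
#' @export
mg_loss_rate <- function(mask) {
  check_mask(mask)
  lid <- sum(mask == 1 | mask == 2)
  if (lid == 0) stop_param("loss rate undefined: no eyelid-area pixels")
  min(max(1 - sum(mask == 2) / lid, 0), 1)
}

#' Meiboscore grade of a loss rate
#'
#' Clinical 0-3 grading of gland atrophy in one-third (33%) increments:
#' grade 0 for no loss, 1 for loss in (0, 1/3\], 2 for (1/3, 2/3\], 3
#' above 2/3.
#'
#' @param rate loss rate(s) in \[0,1\] (vectorized).
#' @return integer grade(s) in \{0,1,2,3\}.
#' @export
meiboscore <- function(rate) {
  if (any(rate < 0 | rate > 1)) stop_param("rate must lie in [0,1]")
  ifelse(rate == 0, 0L,
         ifelse(rate <= 1 / 3, 1L, ifelse(rate <= 2 / 3, 2L, 3L)))
}

#' Root-mean-squared error between predicted and true loss rates
#'
#' @param records data frame (or list of lists) with columns
#'   `predicted_rate` and `true_rate`, or two numeric vectors via
#'   `predicted` / `true`.
#' @param predicted,true alternative vector interface.
#' @return scalar RMSE.
#' @export
loss_rate_rmse <- function(records = NULL, predicted = NULL, true = NULL) {
  if (!is.null(records)) {
    if (!is.data.frame(records)) records <- do.call(rbind.data.frame, records)
    predicted <- records$predicted_rate; true <- records$true_rate
  }
  if (length(predicted) == 0) stop_param("no loss-rate records supplied")
  sqrt(mean((predicted - true)^2))
}

#' Mann-Whitney comparison of two metric samples
#'
#' Two-sided Mann-Whitney U test (exact for small tie-free samples,
#' normal approximation with tie correction otherwise), flagging
#' significance at p < 0.01.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param metric optional metric name carried into the result.
#' @param alpha significance level (default 0.01).
#' @return list with `metric`, `U` (statistic for the first sample),
#'   `p_value`, `significant`.
#' @export
compare_groups <- function(a, b, metric = NA_character_, alpha = 0.01) {
  if (length(a) < 2 || length(b) < 2)
    stop_param("both samples must have at least 2 observations")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  list(metric = metric, U = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha)
}

#' Evaluate a model over a labelled dataset
#'
#' Runs [predict_mask()] on every image, computes per-region metrics and
#' the predicted/true MG loss rates and meiboscores.
#'
#' @param model an `mgseg_net` or `mgseg_fit`.
#' @param dataset list of `labeled_image` objects.
#' @param condition label recorded in the output (e.g. "internal+clahe").
#' @param preprocess optional function applied to each image before
#'   prediction (e.g. CLAHE or histogram specification).
#' @return list with data frames `metrics` (image_id, condition, region,
#'   dsc, recall, precision, flagged) and `loss_rates` (image_id,
#'   condition, predicted_rate, true_rate, predicted_grade, true_grade).
#' @export
evaluate_dataset <- function(model, dataset, condition = "test",
                             preprocess = NULL) {
  met <- list(); lr <- list()
  for (i in seq_along(dataset)) {
    it <- dataset[[i]]
    img <- if (is.null(preprocess)) it$image else preprocess(it$image)
    pred <- predict_mask(model, img)
    for (r in 1:2) {
      m <- region_metrics(pred, it$mask, r, image_id = i)
      met[[length(met) + 1]] <- data.frame(
        image_id = i, condition = condition, region = m$region,
        dsc = m$dsc, recall = m$recall, precision = m$precision,
        flagged = m$flagged)
    }
    pr <- tryCatch(mg_loss_rate(pred), error = function(e) NA_real_)
    tr <- mg_loss_rate(it$mask)
    lr[[length(lr) + 1]] <- data.frame(
      image_id = i, condition = condition,
      predicted_rate = pr, true_rate = tr,
      predicted_grade = if (is.na(pr)) NA_integer_ else meiboscore(pr),
      true_grade = meiboscore(tr))
  }
  list(metrics = do.call(rbind, met), loss_rates = do.call(rbind, lr))
}

#' Aggregate per-image metrics as mean and SD per condition and region
#'
#' Flagged records (empty truth region) are excluded; the number of
#' exclusions is reported.
#'
#' @param metrics the `metrics` data frame from [evaluate_dataset()].
#' @return data frame with one row per condition x region.
#' @export
aggregate_metrics <- function(metrics) {
  out <- list()
  for (cond in unique(metrics$condition))
    for (reg in unique(metrics$region)) {
      m <- metrics[metrics$condition == cond & metrics$region == reg, ]
      keep <- m[!m$flagged, ]
      out[[length(out) + 1]] <- data.frame(
        condition = cond, region = reg, n = nrow(keep),
        excluded = sum(m$flagged),
        dsc_mean = mean(keep$dsc), dsc_sd = sd(keep$dsc),
        recall_mean = mean(keep$recall), recall_sd = sd(keep$recall),
        precision_mean = mean(keep$precision, na.rm = TRUE),
        precision_sd = sd(keep$precision, na.rm = TRUE))
    }
  do.call(rbind, out)
}
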