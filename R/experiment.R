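# The six-condition cross-device experiment: train on the internal-device
# style (raw and CLAHE-preprocessed variants), test on internal and
# external styles under the preprocessing combinations
# {none, CLAHE} x {internal} and {none, HS, CLAHE, HS+CLAHE} x {external},
# with the HS template computed from the internal-style image pool.

ALL_CONDITIONS <- c("internal", "internal+clahe", "external", "external+hs",
                    "external+clahe", "external+hs+clahe")

#' Experiment configuration
#'
#' @param internal_style,external_style [device_style()] objects for the
#'   training-device and deployment-device image populations.
#' @param conditions subset of the six testing conditions.
#' @param n_train,n_val,n_test number of phantoms for training,
#'   validation, and each testing set.
#' @param image_size phantom side length, pixels.
#' @param model a [network_config()].
#' @param train a [train_config()].
#' @param augment an [augment_config()] for the 12-fold training-set
#'   expansion, or `NULL` to train on the raw set.
#' @param clahe a [clahe_params()].
#' @param atrophy_range atrophy sampling range for the phantoms.
#' @param clahe_model_for_clahe_conditions score CLAHE-preprocessed
#'   testing sets with the CLAHE-trained model (default) rather than the
#'   raw-trained model.
#' @param seed master seed; all dataset, initialization and training
#'   randomness derives from it.
#' @param out_dir optional directory for the CSV outputs.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(internal_style = style_internal(),
                              external_style = style_external(),
                              conditions = ALL_CONDITIONS,
                              n_train = 60, n_val = 10, n_test = 20,
                              image_size = 64,
                              model = network_config(width_scale = 0.25,
                                                     input_size = 64),
                              train = train_config(batch_size = 8,
                                                   max_epochs = 20,
                                                   input_size = 64),
                              augment = NULL,
                              clahe = NULL,
                              atrophy_range = c(0, 0.8),
                              clahe_model_for_clahe_conditions = TRUE,
                              seed = 1L, out_dir = NULL) {
  if (!length(conditions) || !all(conditions %in% ALL_CONDITIONS))
    stop_param("conditions must be a non-empty subset of: %s",
               paste(ALL_CONDITIONS, collapse = ", "))
  clahe <- clahe %||% clahe_params(tile_size = max(8, image_size / 4))
  structure(list(internal_style = internal_style,
                 external_style = external_style, conditions = conditions,
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 image_size = image_size, model = model, train = train,
                 augment = augment, clahe = clahe,
                 atrophy_range = atrophy_range,
                 clahe_model_for_clahe_conditions =
                   clahe_model_for_clahe_conditions,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

clahe_set <- function(dataset, params) {
  lapply(dataset, function(it) { it$image <- clahe(it$image, params); it })
}

#' Run the cross-device experiment
#'
#' Generates the internal-style training/validation/testing sets and the
#' external-style testing set, optionally expands the training set
#' 12-fold, trains the raw-image model and (when a CLAHE condition is
#' requested) the CLAHE-image model, evaluates every requested condition
#' with its matching model, and assembles metric tables, loss-rate RMSE,
#' Mann-Whitney comparisons between conditions, and the histogram-gap and
#' embedding diagnostics.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return a `mgseg_experiment` list: `metrics`, `metrics_summary`,
#'   `loss_rates`, `rmse`, `comparisons`, `histogram_gap`, `embedding`,
#'   `models`, `config`, `seed`, `package_version`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  samp <- phantom_sampler(height = config$image_size,
                          width = config$image_size,
                          atrophy_range = config$atrophy_range)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating datasets (seed %d)", seed)
  train_set <- generate_dataset(config$n_train, samp, config$internal_style,
                                seed = derive_seed(seed, 11))
  val_set <- if (config$n_val > 0)
    generate_dataset(config$n_val, samp, config$internal_style,
                     seed = derive_seed(seed, 12))
  test_int <- generate_dataset(config$n_test, samp, config$internal_style,
                               seed = derive_seed(seed, 13))
  test_ext <- generate_dataset(config$n_test, samp, config$external_style,
                               seed = derive_seed(seed, 14))

  # HS template from the internal-style image pool available at this point
  template <- average_histogram(c(train_set, test_int), source_set = "internal")

  if (!is.null(config$augment)) {
    say("augmenting training set 12-fold")
    train_set <- augment_dataset(train_set, config$augment)
  }

  model_cfg <- config$model
  model_cfg$seed <- derive_seed(seed, 21)
  tcfg <- config$train
  tcfg$seed <- derive_seed(seed, 22)
  say("training raw-image model (%d images)", length(train_set))
  fit_raw <- fit_network(build_network(model_cfg), train_set, val_set, tcfg,
                         verbose = verbose)

  need_clahe <- any(grepl("clahe", config$conditions)) &&
    config$clahe_model_for_clahe_conditions
  fit_clahe <- NULL
  if (need_clahe) {
    say("training CLAHE-image model")
    model_cfg$seed <- derive_seed(seed, 23)
    tcfg$seed <- derive_seed(seed, 24)
    fit_clahe <- fit_network(build_network(model_cfg),
                             clahe_set(train_set, config$clahe),
                             if (!is.null(val_set))
                               clahe_set(val_set, config$clahe),
                             tcfg, verbose = verbose)
  }

  hs_fun <- function(img) specify_histogram(img, template)$image
  cl_fun <- function(img) clahe(img, config$clahe)
  plan <- list(
    "internal" = list(set = test_int, model = "raw", pre = NULL),
    "internal+clahe" = list(set = test_int, model = "clahe", pre = cl_fun),
    "external" = list(set = test_ext, model = "raw", pre = NULL),
    "external+hs" = list(set = test_ext, model = "raw", pre = hs_fun),
    "external+clahe" = list(set = test_ext, model = "clahe", pre = cl_fun),
    "external+hs+clahe" = list(set = test_ext, model = "clahe",
                               pre = function(img) cl_fun(hs_fun(img))))

  metrics <- list(); loss_rates <- list()
  for (cond in config$conditions) {
    p <- plan[[cond]]
    model <- if (p$model == "clahe" && !is.null(fit_clahe)) fit_clahe
             else fit_raw
    say("evaluating condition %s", cond)
    ev <- evaluate_dataset(model, p$set, condition = cond, preprocess = p$pre)
    metrics[[cond]] <- ev$metrics
    loss_rates[[cond]] <- ev$loss_rates
  }
  metrics <- do.call(rbind, metrics)
  loss_rates <- do.call(rbind, loss_rates)

  rmse <- do.call(rbind, lapply(split(loss_rates, loss_rates$condition),
    function(d) {
      ok <- stats::complete.cases(d$predicted_rate, d$true_rate)
      data.frame(condition = d$condition[1],
                 rmse = loss_rate_rmse(predicted = d$predicted_rate[ok],
                                       true = d$true_rate[ok]))
    }))
  rownames(rmse) <- NULL

  # pairwise Mann-Whitney comparisons between preprocessing variants of
  # the same testing population, per region and metric
  pairs <- list(c("external", "external+hs"),
                c("external", "external+clahe"),
                c("internal", "internal+clahe"))
  comparisons <- list()
  for (pr in pairs) {
    if (!all(pr %in% config$conditions)) next
    for (reg in c("MG", "eyelid"))
      for (mt in c("dsc", "recall", "precision")) {
        a <- metrics[metrics$condition == pr[1] & metrics$region == reg &
                       !metrics$flagged, mt]
        b <- metrics[metrics$condition == pr[2] & metrics$region == reg &
                       !metrics$flagged, mt]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) next
        cg <- compare_groups(a, b, metric = mt)
        comparisons[[length(comparisons) + 1]] <- data.frame(
          pair = paste(pr, collapse = " vs "), region = reg, metric = mt,
          U = cg$U, p_value = cg$p_value, significant = cg$significant)
      }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)

  gap <- style_histogram_gap(test_int, test_ext)
  emb <- domain_embedding(test_int, test_ext, seed = derive_seed(seed, 31))

  report <- structure(list(
    metrics = metrics, metrics_summary = aggregate_metrics(metrics),
    loss_rates = loss_rates, rmse = rmse, comparisons = comparisons,
    histogram_gap = gap, embedding = emb,
    models = list(raw = fit_raw, clahe = fit_clahe),
    config = config, seed = seed,
    package_version = as.character(utils::packageVersion("meibseg"))),
    class = "mgseg_experiment")

  if (!is.null(config$out_dir)) write_experiment(report, config$out_dir)
  report
}

#' @export
print.mgseg_experiment <- function(x, ...) {
  cat(sprintf("<mgseg_experiment> seed %d, %d conditions, histogram gap %.3f\n",
              x$seed, length(unique(x$metrics$condition)), x$histogram_gap))
  print(x$metrics_summary[, c("condition", "region", "dsc_mean", "dsc_sd")])
  invisible(x)
}

write_experiment <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(report$metrics_summary, file.path(dir, "metrics_summary.csv"),
            row.names = FALSE)
  write.csv(report$loss_rates, file.path(dir, "loss_rates.csv"),
            row.names = FALSE)
  write.csv(report$rmse, file.path(dir, "rmse.csv"), row.names = FALSE)
  if (!is.null(report$comparisons))
    write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
              row.names = FALSE)
  write.csv(report$embedding$coords, file.path(dir, "embedding.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$seed, package_version = report$package_version,
         histogram_gap = report$histogram_gap,
         conditions = unique(report$metrics$condition)),
    file.path(dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
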