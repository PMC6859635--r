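#' Full analysis pipeline
#'
#' Orchestrates the complete workflow for one rootstock: load the
#' per-medium data (or generate synthetic replicates), split into training
#' and test sets, fit the requested models, compute comparison metrics on
#' the test set, optimize the published response surfaces, and write all
#' tables plus the run configuration to an output directory.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param rootstock `"Pyrodwarf"` or `"OHF"`.
#' @param responses Responses to model (default all five).
#' @param data_source `"paper"` (packaged per-medium means) or
#'   `"synthetic"` (replicate-level records from [spec_from_published()]).
#' @param noise_sd Noise SD passed to [spec_from_published()] when
#'   `data_source = "synthetic"`.
#' @param replicates Replicates per medium for synthetic data.
#' @param models Subset of `c("gep", "rbfnn", "mlr")` to fit.
#' @param train_fraction,seed Train/test split parameters.
#' @param gep A [gep_config()].
#' @param rbf_hidden,rbf_epochs,rbf_learning_rate RBF settings.
#' @param ga A [ga_config()].
#' @param optimize Run the GA over the published models (default `TRUE`).
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @return A `run_config` list.
#' @export
run_config <- function(rootstock = "Pyrodwarf",
                       responses = response_names(),
                       data_source = c("paper", "synthetic"),
                       noise_sd = NULL, replicates = 10,
                       models = c("gep", "rbfnn", "mlr"),
                       train_fraction = 0.7, seed = 1,
                       gep = gep_config(),
                       rbf_hidden = 10, rbf_epochs = 500,
                       rbf_learning_rate = 0.05,
                       ga = ga_config(), optimize = TRUE,
                       out_dir = NULL) {
  data_source <- match.arg(data_source)
  models <- match.arg(models, several.ok = TRUE)
  bad <- setdiff(responses, response_names())
  if (length(bad) > 0) {
    stop("invalid config field 'responses': unknown response(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(rootstock = match_rootstock(rootstock),
                 responses = responses, data_source = data_source,
                 noise_sd = noise_sd, replicates = replicates,
                 models = models, train_fraction = train_fraction,
                 seed = seed, gep = gep, rbf_hidden = rbf_hidden,
                 rbf_epochs = rbf_epochs,
                 rbf_learning_rate = rbf_learning_rate, ga = ga,
                 optimize = optimize, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param config A [run_config()].
#' @return List with `data`, `split`, `models` (per response, per model),
#'   `metrics` (test-set comparison table), `ranking`
#'   (see [compare_models()]) and `optima` (see [optimize_all()]); written
#'   to `config$out_dir` as CSV/JSON when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- if (config$data_source == "paper") {
    load_dataset(config$rootstock)
  } else {
    generate_replicates(load_dataset(config$rootstock),
                        spec_from_published(config$rootstock,
                                            noise_sd = config$noise_sd,
                                            replicates = config$replicates),
                        seed = config$seed)
  }
  split <- split_train_test(data, config$train_fraction, seed = config$seed)
  fits <- list()
  metrics_rows <- list()
  for (rp in config$responses) {
    fits[[rp]] <- list()
    for (mdl in config$models) {
      fit <- switch(mdl,
        gep = {
          cfg <- config$gep
          cfg$seed <- config$seed
          evolve(split$train, rp, cfg)
        },
        rbfnn = train_rbf(split$train, rp, n_hidden = config$rbf_hidden,
                          learning_rate = config$rbf_learning_rate,
                          epochs = config$rbf_epochs, seed = config$seed),
        mlr = fit_mlr(split$train, rp))
      fits[[rp]][[mdl]] <- fit
      pred <- predict(fit, split$test)
      m <- compute_metrics(split$test[[rp]], pred)
      metrics_rows[[length(metrics_rows) + 1]] <-
        cbind(data.frame(rootstock = config$rootstock, response = rp,
                         model = toupper(mdl), stringsAsFactors = FALSE),
              metrics_table(stats::setNames(list(m), mdl))[, -1])
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  ranking <- do.call(rbind, lapply(config$responses, function(rp) {
    compare_models(metrics[metrics$response == rp, ])
  }))
  optima <- if (config$optimize) {
    cfg <- config$ga
    cfg$seed <- config$seed
    optimize_all(config$rootstock, cfg)
  } else NULL
  out <- list(config = config, data = data, split = split, models = fits,
              metrics = metrics, ranking = ranking, optima = optima)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                     row.names = FALSE)
    if (!is.null(optima)) {
      utils::write.csv(optima, file.path(config$out_dir, "optima.csv"),
                       row.names = FALSE)
    }
    cfg_out <- config
    cfg_out$gep <- unclass(cfg_out$gep)
    cfg_out$ga <- unclass(cfg_out$ga)
    jsonlite::write_json(unclass(cfg_out),
                         file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         force = TRUE)
    for (rp in names(fits)) {
      if (!is.null(fits[[rp]]$gep)) {
        writeLines(fits[[rp]]$gep$formula,
                   file.path(config$out_dir,
                             paste0("gep_", rp, "_formula.txt")))
      }
    }
  }
  invisible(out)
}

#' Rank models by test error
#'
#' Orders models by RMSE ascending, breaking ties by higher r-squared.
#'
#' @param metrics Data frame with columns `model`, `rmse`, `r_squared`
#'   (one row per model, as produced by [run_pipeline()] for one response).
#' @return The same rows, ordered, with a `rank` column.
#' @export
compare_models <- function(metrics) {
  stopifnot(all(c("model", "rmse", "r_squared") %in% names(metrics)))
  ord <- order(metrics$rmse, -metrics$r_squared)
  out <- metrics[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
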