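#' Pipeline configuration
#'
#' Resolves and validates every setting of the end-to-end run:
#' simulation, feature extraction, tensor factorization and prediction.
#' The resolved configuration is serialized losslessly to JSON alongside
#' the artifacts, so a run is fully reproducible from its output
#' directory.
#'
#' @param out_dir artifact directory.
#' @param data_dir where recordings + `cohort.csv` live; defaults to
#'   `<out_dir>/data` (populated by the simulate stage).
#' @param simulate named list of [generate_cohort()] arguments (used by the
#'   simulate stage).
#' @param features named list of [feature_config()] arguments.
#' @param rank,gamma,supervised factorization settings.
#' @param k,regressor cross-validation settings.
#' @param seed master seed.
#' @return list of class `neurodyn_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, data_dir = NULL,
                            simulate = list(), features = list(),
                            rank = 3L, gamma = 1, supervised = TRUE,
                            k = 5L, regressor = "random_forest", seed = 1L) {
  fc <- do.call(feature_config, features)   # validates measure names early
  regressor <- match.arg(regressor, c("random_forest", "gradient_boost", "linear"))
  if (is.null(data_dir)) data_dir <- file.path(out_dir, "data")
  structure(list(out_dir = out_dir, data_dir = data_dir,
                 simulate = simulate, features = features,
                 feature_config = fc, rank = as.integer(rank), gamma = gamma,
                 supervised = isTRUE(supervised), k = as.integer(k),
                 regressor = regressor, seed = as.integer(seed)),
            class = "neurodyn_pipeline_config")
}

pipeline_log <- function(cfg, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  cat(msg, "\n", file = file.path(cfg$out_dir, "pipeline.log"), append = TRUE)
}

#' Run the biomarker pipeline
#'
#' Executes the requested stages in order: `simulate` (synthetic cohort to
#' `data_dir`), `features` (per-subject measure tables), `tensor`
#' (fourth-order feature tensor), `factorize` (whole-cohort factor model,
#' for inspection of loadings) and `predict` (per-fold supervised or
#' unsupervised factorization plus cross-validated regression). Each stage
#' is idempotent: existing artifacts are reused unless `force` is set, so
#' a pipeline can resume after deleting any subset of downstream outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "features", "tensor", "factorize",
#'   "predict")`; `"all"` (default) runs every stage.
#' @param force recompute even when artifacts exist.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, stages = "all", force = FALSE) {
  stopifnot(inherits(config, "neurodyn_pipeline_config"))
  all_stages <- c("simulate", "features", "tensor", "factorize", "predict")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config[setdiff(names(config), "feature_config")],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths <- list(
    data = config$data_dir,
    features = file.path(config$out_dir, "features"),
    tensor = file.path(config$out_dir, "tensor"),
    factors = file.path(config$out_dir, "factors"),
    predictions = file.path(config$out_dir, "predictions.csv"),
    results = file.path(config$out_dir, "results.json")
  )

  if ("simulate" %in% stages) {
    if (force || !file.exists(file.path(paths$data, "cohort.csv"))) {
      pipeline_log(config, "simulate: generating synthetic cohort")
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- config$seed
      co <- do.call(generate_cohort, args)
      write_cohort(co, paths$data)
    } else pipeline_log(config, "simulate: artifacts present, skipping")
  }

  if (any(c("features", "tensor", "factorize", "predict") %in% stages)) {
    if (!file.exists(file.path(paths$data, "cohort.csv")))
      stop("stage 'features': no cohort at ", paths$data)
    cohort <- utils::read.csv(file.path(paths$data, "cohort.csv"),
                              stringsAsFactors = FALSE)
  }

  if ("features" %in% stages) {
    dir.create(paths$features, showWarnings = FALSE)
    todo <- cohort$subject_id[force | !file.exists(
      file.path(paths$features, paste0(cohort$subject_id, ".csv")))]
    if (length(todo)) {
      pipeline_log(config, sprintf("features: %d subject(s)", length(todo)))
      for (id in todo) {
        rec <- read_recording(file.path(paths$data, paste0(id, ".csv")))
        ft <- extract_features(rec, config$feature_config)
        utils::write.csv(ft, file.path(paths$features, paste0(id, ".csv")),
                         row.names = FALSE)
      }
    } else pipeline_log(config, "features: artifacts present, skipping")
  }

  if ("tensor" %in% stages) {
    if (force || !file.exists(file.path(paths$tensor, "values.csv"))) {
      pipeline_log(config, "tensor: assembling feature tensor")
      fts <- lapply(cohort$subject_id, function(id) {
        f <- file.path(paths$features, paste0(id, ".csv"))
        if (!file.exists(f)) stop("stage 'tensor': missing features for ", id)
        tb <- utils::read.csv(f, stringsAsFactors = FALSE)
        tb$flags[is.na(tb$flags)] <- ""
        tb
      })
      names(fts) <- cohort$subject_id
      write_tensor(assemble_tensor(fts, cohort), paths$tensor)
    } else pipeline_log(config, "tensor: artifacts present, skipping")
  }

  if ("factorize" %in% stages) {
    if (force || !file.exists(file.path(paths$factors, "subject.csv"))) {
      pipeline_log(config, "factorize: whole-cohort CP model")
      x <- normalize_tensor(read_tensor(paths$tensor))
      fit <- if (config$supervised) {
        supervised_cp(x, config$rank,
                      supervision_spec(cohort$age_months, gamma = config$gamma),
                      seed = config$seed)
      } else cp_decompose(x, config$rank, seed = config$seed)
      dir.create(paths$factors, showWarnings = FALSE)
      for (mode in names(fit$factors)) {
        tb <- data.frame(label = rownames(fit$factors[[mode]]),
                         fit$factors[[mode]], check.names = FALSE)
        names(tb) <- c("label", paste0("factor", seq_len(fit$rank)))
        utils::write.csv(tb, file.path(paths$factors, paste0(mode, ".csv")),
                         row.names = FALSE)
      }
      jsonlite::write_json(list(weights = fit$weights, fit = fit$fit,
                                iterations = fit$iterations,
                                converged = fit$converged),
                           file.path(paths$factors, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    } else pipeline_log(config, "factorize: artifacts present, skipping")
  }

  if ("predict" %in% stages) {
    if (force || !file.exists(paths$results)) {
      pipeline_log(config, "predict: per-fold factorization + CV regression")
      x <- read_tensor(paths$tensor)
      pr <- cv_factor_regress(x, cohort$age_months, rank = config$rank,
                              supervised = config$supervised,
                              gamma = config$gamma, k = config$k,
                              regressor = config$regressor, seed = config$seed)
      utils::write.csv(data.frame(subject_id = cohort$subject_id,
                                  age_months = cohort$age_months,
                                  fold = pr$fold, prediction = pr$prediction),
                       paths$predictions, row.names = FALSE)
      jsonlite::write_json(list(r = pr$r, p = pr$p, mae = pr$mae,
                                per_fold_r = pr$per_fold_r,
                                regressor = pr$regressor,
                                supervised = pr$supervised, seed = pr$seed),
                           paths$results, auto_unbox = TRUE, digits = NA)
    } else pipeline_log(config, "predict: artifacts present, skipping")
  }
  invisible(paths)
}
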