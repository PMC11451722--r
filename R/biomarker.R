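#' Correlation and error metrics for predictions
#'
#' Pooled Pearson correlation (with its two-sided p-value) and mean
#' absolute error between predictions and the target, in target units.
#'
#' @param pred,target equal-length numeric vectors (n >= 3).
#' @return named list `r`, `p`, `mae`.
#' @export
eval_metrics <- function(pred, target) {
  stopifnot(length(pred) == length(target), length(pred) >= 3L)
  if (stats::sd(pred) == 0 || stats::sd(target) == 0)
    stop("zero variance in predictions or target")
  ct <- stats::cor.test(pred, target, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       mae = mean(abs(pred - target)))
}

# fit a regressor on (X, y); returns a predict(newX) closure
fit_regressor <- function(X, y, regressor, seed) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  switch(regressor,
    linear = {
      df <- data.frame(y = y, X)
      mod <- stats::lm(y ~ ., data = df)
      function(newX) {
        newX <- as.matrix(newX)
        colnames(newX) <- colnames(X)
        unname(stats::predict(mod, newdata = as.data.frame(newX)))
      }
    },
    random_forest = {
      mod <- with_seed(seed, randomForest::randomForest(
        x = X, y = y, ntree = 500))
      function(newX) {
        newX <- as.matrix(newX)
        colnames(newX) <- colnames(X)
        unname(stats::predict(mod, newdata = newX))
      }
    },
    gradient_boost = {
      mod <- xgboost::xgboost(
        x = X, y = y, objective = "reg:squarederror", nrounds = 200,
        max_depth = 3, learning_rate = 0.1, subsample = 0.8,
        nthreads = 1, seed = seed, verbosity = 0)
      function(newX) {
        newX <- as.matrix(newX)
        colnames(newX) <- colnames(X)
        unname(stats::predict(mod, newX))
      }
    },
    stop("unknown regressor: ", regressor)
  )
}

# seeded disjoint exhaustive fold assignment
make_folds <- function(n, k, seed) {
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of subjects")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Cross-validated regression of a target on latent scores
#'
#' Seeded k-fold cross-validation: for each fold the regressor is fitted
#' on training subjects only and applied to the held-out fold, every
#' subject is predicted exactly once, and the pooled predictions are
#' scored with [eval_metrics()]. Per-fold correlations are also reported.
#'
#' @param scores numeric matrix subjects x factors (or any feature matrix).
#' @param target numeric target vector (e.g. age in months).
#' @param k number of folds (default 5; requires `N >= 2k`).
#' @param regressor `"random_forest"`, `"gradient_boost"` or `"linear"`.
#' @param seed integer seed controlling folds and regressor randomness.
#' @return object of class `neurodyn_prediction`: list with `prediction`
#'   (per-subject out-of-fold), `fold`, `r`, `p`, `mae`, `per_fold_r`,
#'   `regressor`, `seed`.
#' @export
cv_regress <- function(scores, target, k = 5L,
                       regressor = c("random_forest", "gradient_boost", "linear"),
                       seed = 1L) {
  regressor <- match.arg(regressor)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(target) == n)
  if (stats::sd(target) == 0) stop("constant target")
  k <- as.integer(k)
  if (n < 2L * k) stop("need at least 2k subjects")
  fold <- make_folds(n, k, seed)
  pred <- numeric(n)
  for (fd in seq_len(k)) {
    tr <- fold != fd
    model <- fit_regressor(scores[tr, , drop = FALSE], target[tr],
                           regressor, seed = seed * 100L + fd)
    pred[!tr] <- model(scores[!tr, , drop = FALSE])
  }
  met <- eval_metrics(pred, target)
  per_fold <- vapply(seq_len(k), function(fd) {
    idx <- fold == fd
    if (stats::sd(pred[idx]) == 0 || stats::sd(target[idx]) == 0) return(NA_real_)
    stats::cor(pred[idx], target[idx])
  }, numeric(1))
  structure(list(prediction = pred, fold = fold, r = met$r, p = met$p,
                 mae = met$mae, per_fold_r = per_fold,
                 regressor = regressor, seed = seed),
            class = "neurodyn_prediction")
}

#' @export
print.neurodyn_prediction <- function(x, ...) {
  cat(sprintf("<neurodyn_prediction> %s, %d folds: r = %.3f (p = %.3g), MAE = %.2f\n",
              x$regressor, max(x$fold), x$r, x$p, x$mae))
  invisible(x)
}

#' Cross-validated latent-factor extraction and target regression
#'
#' The full per-fold protocol of the biomarker pipeline: within each
#' training fold the feature tensor is normalized (statistics estimated on
#' training subjects only), factorized — supervised by the training
#' targets, or unsupervised — and the held-out subjects are scored by
#' projection onto the fold's non-subject factors before the regressor
#' maps scores to the target. Held-out targets are never visible to
#' normalization, factorization or regression, so fold predictions are
#' leakage-free.
#'
#' @param x a [feature_tensor()] (raw, un-normalized).
#' @param target numeric target vector aligned with the subject axis.
#' @param rank CP rank (default 3).
#' @param supervised logical; couple the factorization to the target
#'   (default `TRUE`).
#' @param gamma,covariates,ridge supervision settings, see
#'   [supervision_spec()].
#' @param k folds (default 5).
#' @param regressor see [cv_regress()].
#' @param seed integer seed (folds, factorization starts, regressor).
#' @param n_starts random ALS starts per fold (default 3).
#' @param max_iter ALS sweep cap per start (default 200).
#' @return a `neurodyn_prediction` with additional elements `scores`
#'   (pooled out-of-fold subject scores) and `supervised`.
#' @export
cv_factor_regress <- function(x, target, rank = 3L, supervised = TRUE,
                              gamma = 1, covariates = NULL, ridge = 1e-6,
                              k = 5L, regressor = "random_forest", seed = 1L,
                              n_starts = 3L, max_iter = 200L) {
  stopifnot(inherits(x, "neurodyn_tensor"))
  n <- dim(x$values)[1L]
  stopifnot(length(target) == n)
  k <- as.integer(k)
  if (n < 2L * k) stop("need at least 2k subjects")
  fold <- make_folds(n, k, seed)
  pred <- numeric(n)
  scores_all <- matrix(NA_real_, n, rank)
  for (fd in seq_len(k)) {
    tr <- fold != fd
    xtr <- subset_tensor(x, tr)
    xte <- subset_tensor(x, !tr)
    ntr <- normalize_tensor(xtr)
    nte <- normalize_tensor(xte, center = attr(ntr, "center"),
                            scale = attr(ntr, "scale"))
    fit <- if (supervised) {
      sup <- supervision_spec(target[tr],
                              covariates = if (is.null(covariates)) NULL
                                           else covariates[tr, , drop = FALSE],
                              gamma = gamma, ridge = ridge)
      supervised_cp(ntr, rank, sup, seed = seed * 10L + fd,
                    n_starts = n_starts, max_iter = max_iter)
    } else {
      cp_decompose(ntr, rank, seed = seed * 10L + fd,
                   n_starts = n_starts, max_iter = max_iter)
    }
    # train and test scores go through the identical projection path, so the
    # regressor sees one score distribution (ALS scores additionally carry
    # the supervision pull and would be distributed differently)
    str_ <- project_subjects(fit, ntr)
    ste <- project_subjects(fit, nte)
    model <- fit_regressor(str_, target[tr], regressor, seed = seed * 100L + fd)
    pred[!tr] <- model(ste)
    scores_all[!tr, ] <- ste
  }
  met <- eval_metrics(pred, target)
  per_fold <- vapply(seq_len(k), function(fd) {
    idx <- fold == fd
    if (stats::sd(pred[idx]) == 0 || stats::sd(target[idx]) == 0) return(NA_real_)
    stats::cor(pred[idx], target[idx])
  }, numeric(1))
  structure(list(prediction = pred, fold = fold, r = met$r, p = met$p,
                 mae = met$mae, per_fold_r = per_fold, scores = scores_all,
                 regressor = regressor, supervised = supervised, seed = seed),
            class = "neurodyn_prediction")
}

# tensor restricted to a logical/integer subject subset
subset_tensor <- function(x, idx) {
  feature_tensor(x$values[idx, , , , drop = FALSE],
                 x$mask[idx, , , , drop = FALSE])
}
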