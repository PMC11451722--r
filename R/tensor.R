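#' Feature tensor container
#'
#' A fourth-order array of dynamical measures, subjects x sensors x bands x
#' measures, with axis labels and a missing/quality mask. Masked cells hold
#' placeholder 0 and are excluded from normalization and factorization.
#'
#' @param values 4-way numeric array with complete `dimnames`.
#' @param mask logical array of the same shape; `TRUE` = missing/flagged.
#' @return object of class `neurodyn_tensor`.
#' @export
feature_tensor <- function(values, mask = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 4L,
            !is.null(dimnames(values)))
  if (is.null(mask)) mask <- array(FALSE, dim = dim(values))
  stopifnot(all(dim(mask) == dim(values)))
  dimnames(mask) <- dimnames(values)
  values[mask] <- 0
  structure(list(values = values, mask = mask), class = "neurodyn_tensor")
}

#' @export
print.neurodyn_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<neurodyn_tensor> %d subjects x %d sensors x %d bands x %d measures (%.1f%% masked)\n",
              d[1], d[2], d[3], d[4], 100 * mean(x$mask)))
  invisible(x)
}

#' Assemble per-subject feature tables into the fourth-order tensor
#'
#' Stacks the [extract_features()] tables of all subjects into a
#' subjects x sensors x bands x measures array. Subjects follow the cohort
#' table's row order; channel, band and measure labels are sorted so the
#' axis ordering is reproducible. Flagged measures are masked; a subject
#' lacking a (channel, band) row has that slice fully masked.
#'
#' @param feature_tables named list (by subject id) of feature data.frames.
#' @param cohort data.frame with a `subject_id` column defining subject
#'   order (defaults to the list names' order).
#' @return a [feature_tensor()].
#' @export
assemble_tensor <- function(feature_tables, cohort = NULL) {
  ids <- names(feature_tables)
  if (is.null(ids) || any(!nzchar(ids))) stop("feature_tables must be named by subject id")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  if (!is.null(cohort)) {
    if (!all(ids %in% cohort$subject_id) || !all(cohort$subject_id %in% ids))
      stop("subject ids do not match the cohort table")
    ids <- as.character(cohort$subject_id)
  }
  meta_cols <- c("channel", "band", "flags")
  measure_sets <- lapply(feature_tables, function(tb) sort(setdiff(names(tb), meta_cols)))
  if (length(unique(measure_sets)) != 1L)
    stop("subjects disagree on the measure set")
  measures <- measure_sets[[1L]]
  chans <- sort(unique(unlist(lapply(feature_tables, function(tb) tb$channel))))
  bands <- sort(unique(unlist(lapply(feature_tables, function(tb) tb$band))))
  dn <- list(subject = ids, sensor = chans, band = bands, measure = measures)
  vals <- array(0, dim = unname(lengths(dn)), dimnames = dn)
  mask <- array(TRUE, dim = unname(lengths(dn)), dimnames = dn)
  for (s in ids) {
    tb <- feature_tables[[s]]
    for (rix in seq_len(nrow(tb))) {
      ch <- tb$channel[rix]; bd <- tb$band[rix]
      flg <- strsplit(tb$flags[rix], ";", fixed = TRUE)[[1L]]
      for (ms in measures) {
        vals[s, ch, bd, ms] <- tb[[ms]][rix]
        mask[s, ch, bd, ms] <- ms %in% flg
      }
    }
  }
  feature_tensor(vals, mask)
}

#' Normalize a feature tensor per measure
#'
#' Z-scores each measure slice over its unmasked entries (measures span
#' incompatible scales; without this a single large-magnitude measure
#' dominates the factorization). Constant slices become zeros and are
#' flagged. Centers and scales are stored so [denormalize_tensor()] can
#' invert the transform.
#'
#' @param x a [feature_tensor()].
#' @param scheme only `"zscore_per_measure"`.
#' @param center,scale optional precomputed per-measure statistics (e.g.
#'   from a training subset) to apply instead of estimating from `x`.
#' @return normalized [feature_tensor()] with attributes `center`, `scale`,
#'   `constant` (flagged measure names).
#' @export
normalize_tensor <- function(x, scheme = "zscore_per_measure",
                             center = NULL, scale = NULL) {
  scheme <- match.arg(scheme, "zscore_per_measure")
  stopifnot(inherits(x, "neurodyn_tensor"))
  measures <- dimnames(x$values)[[4L]]
  est <- is.null(center)
  if (est) {
    center <- stats::setNames(numeric(length(measures)), measures)
    scale <- stats::setNames(numeric(length(measures)), measures)
  }
  constant <- character(0)
  vals <- x$values
  for (ms in measures) {
    v <- vals[, , , ms, drop = FALSE]
    mk <- x$mask[, , , ms, drop = FALSE]
    if (est) {
      u <- v[!mk]
      if (length(u) < 2L) { center[ms] <- 0; scale[ms] <- 1; constant <- c(constant, ms); next }
      center[ms] <- mean(u)
      scale[ms] <- stats::sd(u)
      if (scale[ms] == 0) { scale[ms] <- 1; constant <- c(constant, ms) }
    }
    v <- (v - center[ms]) / scale[ms]
    v[mk] <- 0
    if (ms %in% constant) v[] <- 0
    vals[, , , ms] <- v
  }
  out <- feature_tensor(vals, x$mask)
  attributes(out) <- c(attributes(out),
                       list(center = center, scale = scale, constant = constant))
  out
}

#' @rdname normalize_tensor
#' @export
denormalize_tensor <- function(x) {
  center <- attr(x, "center"); scale <- attr(x, "scale")
  if (is.null(center)) stop("tensor carries no normalization record")
  vals <- x$values
  for (ms in dimnames(vals)[[4L]])
    vals[, , , ms] <- vals[, , , ms] * scale[ms] + center[ms]
  vals[x$mask] <- 0
  feature_tensor(vals, x$mask)
}

# Khatri-Rao product with Y's rows varying fastest
kr2 <- function(X, Y) {
  R <- ncol(X)
  out <- matrix(0, nrow(X) * nrow(Y), R)
  for (r in seq_len(R)) out[, r] <- as.vector(Y[, r] %o% X[, r])
  out
}

# mode-k unfolding: rows = mode k, columns = remaining modes in increasing
# order with the earliest remaining mode varying fastest
unfold <- function(A, k) {
  d <- dim(A)
  perm <- c(k, setdiff(seq_along(d), k))
  matrix(aperm(A, perm), nrow = d[k])
}

# reconstruction array from factor matrices + weights
cp_reconstruct <- function(factors, weights, dims) {
  Z <- kr2(kr2(factors[[4L]], factors[[3L]]), factors[[2L]])
  M <- (factors[[1L]] %*% diag(weights, nrow = length(weights))) %*% t(Z)
  array(M, dim = dims)
}

#' Supervision settings for the tensor factorization
#'
#' @param target numeric target vector, one value per subject (standardized
#'   internally for the coupling term).
#' @param covariates optional numeric matrix (subjects x covariates)
#'   appended to the subject scores in the coupled regression.
#' @param gamma coupling weight >= 0; 0 reduces the factorization to the
#'   unsupervised case. The coupling shrinks subject scores toward the span
#'   of the target (and covariates): score variance orthogonal to that span
#'   is charged `gamma` times the reconstruction it buys, so `gamma = 1`
#'   (default) trades the two one-for-one and large values drive every
#'   component's subject variation toward the target direction.
#' @param ridge ridge penalty on the coupling regression (default 1e-6).
#' @return list of class `neurodyn_supervision`.
#' @export
supervision_spec <- function(target, covariates = NULL, gamma = 1, ridge = 1e-6) {
  stopifnot(is.numeric(target), all(is.finite(target)))
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(target))
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1L)
      stop("covariates are rank deficient")
  }
  structure(list(target = target, covariates = covariates,
                 gamma = gamma, ridge = ridge),
            class = "neurodyn_supervision")
}

#' Canonical polyadic decomposition by alternating least squares
#'
#' Factorizes the feature tensor into `rank` rank-1 components by masked
#' ALS: masked cells are imputed with the current reconstruction each sweep
#' (EM-style), so they never influence the fit. Initialization is the best
#' of `n_starts` seeded random starts by final objective. Factor columns
#' are unit-normalized with the scale absorbed into `weights`, components
#' sorted by descending weight, and signs fixed deterministically
#' (non-subject modes have positive dominant loadings).
#'
#' `supervised_cp()` designates one component as target-aligned: its
#' subject scores u are shrunk toward the span of the (standardized) target
#' and covariates with the penalty `gamma * ||u - W beta||^2` (ridge on
#' beta), alternated with the factor updates, so that component's sensor/
#' band/measure loadings converge to the target-covariant feature pattern
#' while the remaining components model the dominant residual structure
#' unsupervised. `gamma = 0` reproduces `cp_decompose()` exactly.
#' Out-of-sample subjects are scored by [project_subjects()], which never
#' sees their targets.
#'
#' @param x a [feature_tensor()].
#' @param rank number of components R >= 1.
#' @param sup a [supervision_spec()] (supervised variant only).
#' @param seed integer seed for the random starts.
#' @param tol relative objective change for convergence (default 1e-8).
#' @param max_iter maximal ALS sweeps per start (default 500).
#' @param n_starts random starts (default 5).
#' @return object of class `neurodyn_cp`: list with `weights`, `factors`
#'   (list subject/sensor/band/measure), `rank`, `fit` (explained fit),
#'   `iterations`, `converged`, `seed`, `beta` (supervised only),
#'   `objective`.
#' @export
cp_decompose <- function(x, rank, seed = 1L, tol = 1e-8, max_iter = 500L,
                         n_starts = 5L) {
  supervised_cp(x, rank, sup = NULL, seed = seed, tol = tol,
                max_iter = max_iter, n_starts = n_starts)
}

#' @rdname cp_decompose
#' @export
supervised_cp <- function(x, rank, sup = NULL, seed = 1L, tol = 1e-8,
                          max_iter = 500L, n_starts = 5L) {
  stopifnot(inherits(x, "neurodyn_tensor"))
  dims <- dim(x$values)
  rank <- as.integer(rank)
  stopifnot(rank >= 1L)
  gamma_abs <- 0
  y <- NULL; Xc <- NULL; ridge <- 1e-6
  if (!is.null(sup)) {
    stopifnot(inherits(sup, "neurodyn_supervision"))
    if (length(sup$target) != dims[1L])
      stop("supervision target length must equal the subject dimension")
    y <- as.numeric(scale(sup$target))
    if (stats::sd(sup$target) == 0) stop("constant target")
    Xc <- sup$covariates
    ridge <- sup$ridge
    # dimensionless trade-off: off-target score variance of a component is
    # charged gamma times the reconstruction it buys
    gamma_abs <- sup$gamma
  }
  best <- NULL
  for (st in seq_len(n_starts)) {
    res <- cp_als_once(x$values, x$mask, rank, gamma_abs, y, Xc, ridge,
                       seed = as.integer(seed) * 1000L + st,
                       tol = tol, max_iter = max_iter)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  out <- finalize_cp(best, x)
  out$seed <- seed
  out
}

# One seeded ALS run; returns raw factors + diagnostics.
# Modes 2..4 are renormalized to unit columns every update with the scale
# absorbed into the subject mode, so the subject factor's column norms are
# the component magnitudes, pinned by the tensor fit. Without this the
# supervision coupling is vacuous: the subject factor can shed its
# target-aligned component while beta inflates to compensate (the product
# A beta is scale-invariant across modes), leaving the projectable basis
# untouched by the target.
cp_als_once <- function(vals, mask, rank, gamma_abs, y, Xc, ridge,
                        seed, tol, max_iter) {
  dims <- dim(vals)
  n_modes <- 4L
  factors <- with_seed(seed, lapply(dims, function(d)
    matrix(stats::rnorm(d * rank), d, rank)))
  for (k in 2:4) {                       # start from unit-norm non-subject modes
    nv <- sqrt(colSums(factors[[k]]^2)); nv[nv == 0] <- 1
    factors[[k]] <- sweep(factors[[k]], 2L, nv, "/")
  }
  any_mask <- any(mask)
  X <- vals
  if (any_mask) X[mask] <- 0
  beta <- NULL
  W <- if (gamma_abs > 0) {
    if (is.null(Xc)) cbind(y) else cbind(y, Xc)
  } else NULL
  obj_prev <- Inf
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    gram <- lapply(factors, crossprod)
    for (k in seq_len(n_modes)) {
      others <- setdiff(seq_len(n_modes), k)
      Z <- Reduce(function(acc, Fj) kr2(Fj, acc),
                  factors[others][-1L], factors[[others[1L]]])
      V <- Reduce(`*`, gram[others])
      RHS <- unfold(X, k) %*% Z
      if (k == 1L && gamma_abs > 0) {
        # the designated component's scores are shrunk toward the span of
        # [target, covariates]: its subject-score variance orthogonal to
        # that span is charged gamma times the reconstruction it buys, so
        # its loadings converge to the target-covariant feature pattern
        # while the remaining components stay free
        V[1L, 1L] <- V[1L, 1L] + gamma_abs
        if (!is.null(beta))
          RHS[, 1L] <- RHS[, 1L] + gamma_abs * as.numeric(W %*% beta)
      }
      Fk <- t(solve(V + diag(1e-12, rank), t(RHS)))
      if (k > 1L) {                      # unit columns, scale into subject mode
        nv <- sqrt(colSums(Fk^2)); nv[nv == 0] <- 1
        Fk <- sweep(Fk, 2L, nv, "/")
        factors[[1L]] <- sweep(factors[[1L]], 2L, nv, "*")
        gram[[1L]] <- crossprod(factors[[1L]])
      }
      factors[[k]] <- Fk
      gram[[k]] <- crossprod(Fk)
    }
    if (gamma_abs > 0) {
      # regress the supervised component's scores on the target-span design
      beta <- solve(crossprod(W) + diag(ridge, ncol(W)),
                    crossprod(W, factors[[1L]][, 1L]))
    }
    Z1 <- kr2(kr2(factors[[4L]], factors[[3L]]), factors[[2L]])
    recon_mat <- factors[[1L]] %*% t(Z1)
    recon <- array(recon_mat, dim = dims)
    if (any_mask) X[mask] <- recon[mask]       # EM imputation
    res <- (X - recon)[!mask]
    obj <- sum(res^2)
    if (gamma_abs > 0 && !is.null(beta)) {
      obj <- obj + gamma_abs * sum((factors[[1L]][, 1L] - W %*% beta)^2) +
        ridge * sum(beta^2)
    }
    if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, 1e-12)) {
      converged <- TRUE
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  list(factors = factors, beta = beta, objective = obj_prev,
       iterations = iterations, converged = converged)
}

# normalize columns, sort by weight, fix signs, compute fit
finalize_cp <- function(res, x) {
  factors <- res$factors
  rank <- ncol(factors[[1L]])
  norms <- lapply(factors, function(A) {
    nv <- sqrt(colSums(A^2))
    nv[nv == 0] <- 1
    nv
  })
  weights <- Reduce(`*`, norms)
  factors <- Map(function(A, nv) sweep(A, 2L, nv, "/"), factors, norms)
  # deterministic signs: modes 2..4 dominant loading positive, residual sign
  # absorbed into the subject mode
  total_flip <- rep(1, rank)
  for (k in 2:4) {
    s <- vapply(seq_len(rank), function(r) {
      v <- factors[[k]][, r]
      sign(v[which.max(abs(v))])
    }, numeric(1))
    s[s == 0] <- 1
    factors[[k]] <- sweep(factors[[k]], 2L, s, "*")
    factors[[1L]] <- sweep(factors[[1L]], 2L, s, "*")
    total_flip <- total_flip * s
  }
  ord <- order(weights, decreasing = TRUE)
  weights <- weights[ord]
  sign_flips <- total_flip
  factors <- lapply(factors, function(A) A[, ord, drop = FALSE])
  beta <- res$beta
  supervised_component <- NULL
  if (!is.null(beta)) {
    # beta maps the target-span design to the supervised component's raw
    # scores (ALS slot 1); re-express for normalized, sign-fixed scores and
    # record where that component landed after reordering
    beta <- as.numeric(beta) / norms[[1L]][1L] * sign_flips[1L]
    supervised_component <- which(ord == 1L)
  }
  dn <- dimnames(x$values)
  names(factors) <- c("subject", "sensor", "band", "measure")
  for (k in 1:4) rownames(factors[[k]]) <- dn[[k]]
  out <- list(weights = weights, factors = factors, rank = rank,
              beta = beta, supervised_component = supervised_component,
              objective = res$objective,
              iterations = res$iterations, converged = res$converged)
  class(out) <- "neurodyn_cp"
  out$fit <- explained_fit(x, out)
  out
}

#' @export
print.neurodyn_cp <- function(x, ...) {
  cat(sprintf("<neurodyn_cp> rank %d, fit %.4f, %d iteration(s)%s\n",
              x$rank, x$fit, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Explained fit of a CP model
#'
#' `1 - ||T - reconstruction|| / ||T||` over unmasked entries; 1 for a
#' perfect reconstruction, 0 for an all-zero model of a nonzero tensor.
#'
#' @param x a [feature_tensor()].
#' @param fit a `neurodyn_cp`.
#' @return scalar in `(-Inf, 1]`.
#' @export
explained_fit <- function(x, fit) {
  stopifnot(inherits(x, "neurodyn_tensor"), inherits(fit, "neurodyn_cp"))
  recon <- cp_reconstruct(fit$factors, fit$weights, dim(x$values))
  keep <- !x$mask
  denom <- sqrt(sum(x$values[keep]^2))
  if (denom == 0) stop("zero-norm tensor")
  1 - sqrt(sum((x$values[keep] - recon[keep])^2)) / denom
}

#' Score new subjects on fixed non-subject factors
#'
#' Projects held-out subjects' feature slices onto the span of the fitted
#' sensor/band/measure factors by least squares, yielding subject scores
#' comparable to the training scores. No target information is involved,
#' so the projection is safe for out-of-fold evaluation. Masked cells of a
#' subject are dropped from that subject's normal equations.
#'
#' @param fit a `neurodyn_cp`.
#' @param x a [feature_tensor()] of new subjects (same sensor/band/measure
#'   axes, any number of subjects).
#' @return numeric matrix subjects x rank.
#' @export
project_subjects <- function(fit, x) {
  stopifnot(inherits(fit, "neurodyn_cp"), inherits(x, "neurodyn_tensor"))
  Z <- kr2(kr2(fit$factors$measure, fit$factors$band), fit$factors$sensor)
  Zw <- sweep(Z, 2L, fit$weights, "*")
  Xm <- unfold(x$values, 1L)
  Mm <- unfold(x$mask, 1L)
  n <- nrow(Xm)
  S <- matrix(0, n, fit$rank,
              dimnames = list(dimnames(x$values)[[1L]], NULL))
  for (i in seq_len(n)) {
    keep <- !Mm[i, ]
    Zi <- Zw[keep, , drop = FALSE]
    S[i, ] <- solve(crossprod(Zi) + diag(1e-12, fit$rank),
                    crossprod(Zi, Xm[i, keep]))
  }
  S
}
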