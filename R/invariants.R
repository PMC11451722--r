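# -- entropy family -----------------------------------------------------------

# rows = all length-m windows of x (delay 1); optionally only the first
# `rows` of them, as a plain matrix for distance computations
template_matrix <- function(x, m, rows = NULL) {
  n <- length(x)
  np <- n - m + 1L
  tm <- vapply(seq_len(m) - 1L, function(j) x[seq_len(np) + j], numeric(np))
  if (np == 1L) tm <- matrix(tm, nrow = 1L)
  if (!is.null(rows)) tm <- tm[seq_len(rows), , drop = FALSE]
  tm
}

#' Sample entropy
#'
#' The negative natural log of the conditional probability that two
#' sequences matching for `m` points (within tolerance `r`, Chebyshev
#' distance) still match at the point after, self-matches excluded. Lower
#' values indicate more self-similar, less complex signals. Template pairs
#' are counted over the `n - m` windows that have an (m+1)-th continuation,
#' so numerator and denominator range over the same pairs.
#'
#' @param x numeric series, length > m + 1.
#' @param m template length (default 2).
#' @param r tolerance; interpreted as a fraction of `sd(x)` when
#'   `r_is_fraction` (default 0.2), otherwise as an absolute amplitude.
#' @param r_is_fraction see `r`.
#' @return scalar sample entropy (>= 0), with attribute `flag` set to a
#'   reason string when the value is a flagged placeholder 0 (no template
#'   matches, or zero-variance input with fractional `r`).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, r_is_fraction = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  stopifnot(m >= 1L, n > m + 1L, r > 0)
  if (r_is_fraction) {
    sdx <- stats::sd(x)
    if (sdx == 0) return(structure(0, flag = "constant series"))
    r <- r * sdx
  }
  nt <- n - m                       # templates with a continuation
  B <- count_close_pairs(template_matrix(x, m, rows = nt), r)
  A <- count_close_pairs(template_matrix(x, m + 1L), r)
  if (B == 0L) return(structure(0, flag = "no m-template matches"))
  if (A == 0L) return(structure(0, flag = "no (m+1)-template matches"))
  -log(A / B)
}

# number of unordered pairs of rows with Chebyshev distance <= r
count_close_pairs <- function(tm, r) {
  d <- stats::dist(tm, method = "maximum")
  sum(d <= r)
}

#' Approximate and permutation entropy
#'
#' `variant = "approximate"`: Pincus' approximate entropy
#' `phi_m(r) - phi_{m+1}(r)` with self-matches included, where `phi_m` is
#' the mean log frequency of Chebyshev template matches.
#' `variant = "permutation"`: Shannon entropy (natural log) of the ordinal
#' pattern distribution of the given order; ties are broken by order of
#' occurrence (stable sort), optionally normalized by `log(order!)`.
#'
#' @param x numeric series.
#' @param variant `"approximate"` or `"permutation"`.
#' @param m template length for approximate entropy (default 2).
#' @param r tolerance for approximate entropy, fraction of `sd(x)` when
#'   `r_is_fraction`.
#' @param r_is_fraction see `r`.
#' @param order ordinal pattern order for permutation entropy (default 3).
#' @param delay lag between pattern elements (default 1).
#' @param normalize divide permutation entropy by `log(factorial(order))`.
#' @return scalar entropy (>= 0; possibly flagged, see [sample_entropy()]).
#' @export
entropy_variants <- function(x, variant = c("approximate", "permutation"),
                             m = 2L, r = 0.2, r_is_fraction = TRUE,
                             order = 3L, delay = 1L, normalize = FALSE) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  if (variant == "approximate") {
    n <- length(x)
    stopifnot(n > m + 1L, r > 0)
    if (r_is_fraction) {
      sdx <- stats::sd(x)
      if (sdx == 0) return(structure(0, flag = "constant series"))
      r <- r * sdx
    }
    phi <- function(mm) {
      tm <- template_matrix(x, mm)
      dm <- as.matrix(stats::dist(tm, method = "maximum"))
      mean(log(rowMeans(dm <= r)))   # self-match included (diagonal 0 <= r)
    }
    max(0, phi(m) - phi(m + 1L))
  } else {
    order <- as.integer(order); delay <- as.integer(delay)
    stopifnot(order >= 2L, delay >= 1L)
    np <- length(x) - (order - 1L) * delay
    if (np < 2L) stop("series too short for this order/delay")
    idx <- vapply(seq_len(order) - 1L, function(j) x[seq_len(np) + j * delay],
                  numeric(np))
    if (np == 1L) idx <- matrix(idx, nrow = 1L)
    # stable ranking: ties keep order of occurrence
    pats <- apply(idx, 1L, function(w) paste(order(w), collapse = "."))
    p <- table(pats) / length(pats)
    h <- -sum(p * log(p))
    if (normalize) h <- h / log(factorial(order)) else h
  }
}

# -- correlation dimension ----------------------------------------------------

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Estimates the correlation dimension D2 as the slope of
#' `log C(eps)` versus `log eps`, where the correlation sum `C(eps)` is the
#' fraction of embedded point pairs (outside the Theiler window) closer
#' than `eps`. Radii default to a log-spaced grid between small and median
#' pairwise distances; the scaling region is selected automatically as the
#' contiguous radii window (at least half the grid) with the highest
#' goodness of fit R^2.
#'
#' @param x numeric series, or an existing `neurodyn_embedding`.
#' @param m,tau embedding dimension and delay (used when `x` is a series).
#' @param radii optional numeric vector of radii (>= 2 in scaling range).
#' @param theiler Theiler window (default `tau`).
#' @param n_radii grid size when `radii` is NULL (default 20).
#' @return scalar D2 estimate with attributes `r2` (fit quality), `radii`,
#'   `flag` (set when no scaling window reaches R^2 0.9; value then 0).
#' @export
correlation_dimension <- function(x, m = 3L, tau = 1L, radii = NULL,
                                  theiler = NULL, n_radii = 20L) {
  emb <- if (inherits(x, "neurodyn_embedding")) x else delay_embed(x, m, tau)
  if (is.null(theiler)) theiler <- attr(emb, "tau")
  if (is.null(theiler)) theiler <- tau
  dm <- as.matrix(stats::dist(unclass(emb)))
  keep <- abs(row(dm) - col(dm)) > theiler & upper.tri(dm)
  d <- dm[keep]
  corr_dim_from_distances(d, radii, n_radii)
}

# shared GP fitting given the pair-distance multiset
corr_dim_from_distances <- function(d, radii = NULL, n_radii = 20L) {
  d <- d[d > 0]
  if (!length(d)) return(structure(0, flag = "degenerate distances"))
  if (is.null(radii)) {
    # the scaling regime of the correlation sum lives at small scales;
    # larger radii saturate and bias the slope down
    lo <- stats::quantile(d, max(5e-4, 10 / length(d)), names = FALSE)
    hi <- stats::quantile(d, 0.05, names = FALSE)
    if (lo <= 0 || hi <= lo) return(structure(0, flag = "no radius range"))
    radii <- exp(seq(log(lo), log(hi), length.out = n_radii))
  }
  C <- vapply(radii, function(r) mean(d <= r), numeric(1))
  ok <- C > 0
  radii <- radii[ok]; C <- C[ok]
  if (length(radii) < 2L) return(structure(0, flag = "no scaling region"))
  lr <- log(radii); lC <- log(C)
  wlen <- max(5L, ceiling(length(lr) / 2))
  best <- NULL
  for (a in seq_len(length(lr) - wlen + 1L)) {
    b <- a + wlen - 1L
    fit <- stats::lm.fit(cbind(1, lr[a:b]), lC[a:b])
    ssr <- sum(fit$residuals^2)
    sst <- sum((lC[a:b] - mean(lC[a:b]))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 0
    if (is.null(best) || r2 > best$r2)
      best <- list(slope = fit$coefficients[2L], r2 = r2)
  }
  if (best$r2 < 0.9)
    return(structure(0, flag = "no scaling region", r2 = best$r2, radii = radii))
  structure(unname(best$slope), r2 = best$r2, radii = radii)
}

# -- detrended fluctuation analysis ------------------------------------------

#' Detrended fluctuation analysis exponent
#'
#' Computes the DFA scaling exponent alpha: the series is integrated into a
#' profile, split into non-overlapping windows of each scale (taken from
#' both ends so the whole profile is used), each window is detrended by a
#' least-squares polynomial of the given order, and the root-mean-square
#' residual F(s) is regressed on scale in log-log coordinates. Uncorrelated
#' noise gives alpha 0.5; its running sum (Brownian profile) gives 1.5;
#' long-range correlated fGn with Hurst H gives alpha close to H.
#'
#' @param x numeric series.
#' @param scales integer window sizes; default ~12 log-spaced scales between
#'   `4*(order+1)` and `length(x)/4`.
#' @param order detrending polynomial order (default 1, linear).
#' @return scalar alpha with attributes `scales`, `fluctuations`.
#' @export
dfa <- function(x, scales = NULL, order = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  order <- as.integer(order)
  if (is.null(scales)) {
    lo <- 4L * (order + 1L)
    hi <- n %/% 4L
    if (hi <= lo) stop("series too short for DFA")
    scales <- unique(round(exp(seq(log(lo), log(hi), length.out = 12L))))
  }
  scales <- scales[scales >= order + 2L & scales <= n %/% 2L]
  if (length(scales) < 4L) stop("need at least 4 usable scales")
  y <- cumsum(x - mean(x))
  Fs <- vapply(scales, function(s) {
    nw <- n %/% s
    if (nw < 2L) return(NA_real_)
    t_ <- seq_len(s)
    X <- stats::poly(t_, degree = order, raw = TRUE)
    X <- cbind(1, X)
    # windows from the start and from the end
    starts <- c((seq_len(nw) - 1L) * s, n - (seq_len(nw)) * s) + 1L
    res2 <- vapply(starts, function(a) {
      w <- y[a:(a + s - 1L)]
      f <- stats::lm.fit(X, w)
      mean(f$residuals^2)
    }, numeric(1))
    sqrt(mean(res2))
  }, numeric(1))
  ok <- is.finite(Fs) & Fs > 0
  if (sum(ok) < 4L) stop("fewer than 4 scales with two windows")
  fit <- stats::lm.fit(cbind(1, log(scales[ok])), log(Fs[ok]))
  structure(unname(fit$coefficients[2L]),
            scales = scales[ok], fluctuations = Fs[ok])
}

# -- Hurst exponent -----------------------------------------------------------

# Anis-Lloyd-Peters expected R/S of iid Gaussian noise for window n
expected_rs <- function(n) {
  i <- seq_len(n - 1L)
  s <- sum(sqrt((n - i) / i))
  pre <- (n - 0.5) / n
  if (n <= 340) {
    pre * exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi) * s
  } else {
    pre * s / sqrt(n * pi / 2)
  }
}

#' Hurst exponent by rescaled-range analysis
#'
#' Classic R/S estimation over dyadic window sizes: each window's range of
#' the mean-adjusted cumulative sum is divided by its standard deviation
#' and averaged across non-overlapping windows. The small-sample bias of
#' R/S is removed with the Anis-Lloyd-Peters correction: H is 0.5 plus the
#' slope of `log(R/S) - log(E[R/S | iid])` against `log(window)`, so
#' uncorrelated noise maps to 0.5 without the classic upward bias.
#'
#' @param x numeric series, length >= 256.
#' @param method `"rescaled_range"` (only method).
#' @param min_window smallest window (default 64; R/S statistics on shorter
#'   windows are dominated by small-sample bias, which depresses estimates
#'   for persistent series).
#' @param corrected apply the Anis-Lloyd-Peters correction (default `TRUE`).
#' @return scalar H estimate with attributes `windows`, `rs`.
#' @export
hurst_exponent <- function(x, method = "rescaled_range",
                           min_window = 64L, corrected = TRUE) {
  method <- match.arg(method, "rescaled_range")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 256L) stop("need at least 256 samples for R/S estimation")
  hi_exp <- floor(log2(n / 4))
  # short series fall back to smaller windows so that at least four dyadic
  # sizes enter the regression
  lo_exp <- max(3L, min(floor(log2(min_window)), hi_exp - 3L))
  wins <- 2^(seq.int(lo_exp, hi_exp))
  rs <- vapply(wins, function(w) {
    nw <- n %/% w
    vals <- vapply(seq_len(nw), function(k) {
      seg <- x[((k - 1L) * w + 1L):(k * w)]
      s <- stats::sd(seg)
      if (!is.finite(s) || s == 0) return(NA_real_)
      z <- cumsum(seg - mean(seg))
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3L) stop("too few usable windows")
  lw <- log2(wins[ok])
  lr <- log2(rs[ok])
  if (corrected) {
    e <- vapply(wins[ok], expected_rs, numeric(1))
    fit <- stats::lm.fit(cbind(1, lw), lr - log2(e))
    h <- 0.5 + unname(fit$coefficients[2L])
  } else {
    fit <- stats::lm.fit(cbind(1, lw), lr)
    h <- unname(fit$coefficients[2L])
  }
  structure(h, windows = wins[ok], rs = rs[ok])
}

# -- largest Lyapunov exponent ------------------------------------------------

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' For every embedded point the nearest neighbor outside a temporal
#' exclusion window is located; the mean log distance between the pair
#' images after k steps defines the divergence curve, whose initial slope
#' is the largest Lyapunov exponent. The exponent is returned per sample
#' and, when `fs` is given, converted to 1/s.
#'
#' @param x numeric series or `neurodyn_embedding`.
#' @param m,tau embedding parameters (when `x` is a series).
#' @param fit_range integer steps of the divergence curve used for the
#'   slope fit. Default: from 1 to the step where the curve first rises
#'   within 0.5 nats of its saturation level (capped at `k_max`).
#' @param theiler temporal exclusion for neighbor search; defaults to the
#'   series' mean period estimated from mean-crossings (Rosenstein's
#'   recommendation), with floor `(m-1)*tau`.
#' @param k_max longest divergence horizon in samples (default 80).
#' @param fs sampling rate; when given, the exponent is in 1/s.
#' @return scalar exponent with attributes `divergence` (curve),
#'   `fit_range`, `flag` (set when no valid neighbors exist; value 0).
#' @export
lyapunov_max <- function(x, m = 3L, tau = 1L, fit_range = NULL,
                         theiler = NULL, k_max = 80L, fs = NULL) {
  emb <- if (inherits(x, "neurodyn_embedding")) x else delay_embed(x, m, tau)
  if (inherits(x, "neurodyn_embedding")) {
    m <- attr(x, "m"); tau <- attr(x, "tau")
  }
  pts <- unclass(emb)
  np <- nrow(pts)
  if (is.null(theiler)) {
    series <- pts[, 1L]
    crossings <- sum(diff(series > mean(series)) != 0)
    mp <- if (crossings > 0) ceiling(2 * length(series) / crossings) else 10L
    theiler <- max((m - 1L) * tau, min(mp, np %/% 4L))
  }
  k_max <- min(as.integer(k_max), np - 2L)
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  for (k in seq_len(min(theiler, np - 1L))) {
    idx <- seq_len(np - k)
    dm[cbind(idx, idx + k)] <- Inf
    dm[cbind(idx + k, idx)] <- Inf
  }
  usable <- seq_len(np - k_max)   # pairs must have k_max images
  nn <- integer(np); nn[] <- NA_integer_
  for (i in usable) {
    cand <- dm[i, usable]
    j <- which.min(cand)
    if (is.finite(cand[j])) nn[i] <- j
  }
  valid <- usable[!is.na(nn[usable]) & dm[cbind(usable, nn[usable])] > 0]
  if (!length(valid)) return(structure(0, flag = "no valid neighbors"))
  div <- vapply(0:k_max, function(k) {
    dk <- dm[cbind(valid + k, nn[valid] + k)]
    dk <- dk[is.finite(dk) & dk > 0]
    if (!length(dk)) return(NA_real_)
    mean(log(dk))
  }, numeric(1))
  if (all(is.na(div[-1L]))) return(structure(0, flag = "no divergence data"))
  # neighbor separations at floating-point noise level (exactly recurring
  # trajectories) carry no dynamical information
  scale <- stats::median(dm[is.finite(dm)])
  if (is.finite(div[1L]) && div[1L] < log(1e-10 * scale))
    return(structure(0, flag = "degenerate: exact recurrences",
                     divergence = div))
  if (is.null(fit_range)) {
    sat <- max(div, na.rm = TRUE)
    below <- which(div[-1L] < sat - 0.5)       # steps still clearly diverging
    kend <- if (length(below)) max(below) else k_max
    fit_range <- seq_len(max(2L, min(kend, k_max)))
  }
  fit_range <- fit_range[fit_range >= 1L & fit_range <= k_max &
                           is.finite(div[fit_range + 1L])]
  if (length(fit_range) < 2L) return(structure(0, flag = "fit range too short"))
  fit <- stats::lm.fit(cbind(1, fit_range), div[fit_range + 1L])
  lam <- unname(fit$coefficients[2L])
  if (!is.null(fs)) lam <- lam * fs
  structure(lam, divergence = div, fit_range = fit_range, theiler = theiler)
}
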