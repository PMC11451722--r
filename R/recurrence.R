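#' Select an embedding delay from a scalar series
#'
#' Standard heuristics for the delay-embedding lag: the first zero crossing
#' of the autocorrelation function, the first lag where autocorrelation
#' drops below 1/e, or the first local minimum of (binned) mutual
#' information. For a sinusoid the first autocorrelation zero is the quarter
#' period; for white noise all methods return 1.
#'
#' @param x numeric series, length >= 10, non-constant.
#' @param method `"autocorr_zero"`, `"autocorr_1_over_e"` or
#'   `"mutual_info_min"`.
#' @param max_lag largest lag considered (default `length(x) %/% 3`).
#' @return integer delay >= 1, with attribute `method`.
#' @export
select_delay <- function(x, method = c("autocorr_zero", "autocorr_1_over_e",
                                       "mutual_info_min"),
                         max_lag = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) < 10L) stop("series too short (need >= 10 samples)")
  if (stats::sd(x) == 0) stop("constant series: autocorrelation undefined")
  if (is.null(max_lag)) max_lag <- max(2L, length(x) %/% 3L)
  tau <- if (method == "mutual_info_min") {
    mi <- vapply(seq_len(max_lag), function(l) mutual_info_lag(x, l), numeric(1))
    k <- which(diff(mi) > 0)  # first upturn = first local minimum
    if (length(k)) k[1L] else max_lag
  } else {
    rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                                 demean = TRUE)$acf)[-1L]
    # a sample acf value within ~2 standard errors of zero counts as zero,
    # so an analytic zero crossing is not missed by finite-sample jitter
    thr <- if (method == "autocorr_zero") 1.96 / sqrt(length(x)) else exp(-1)
    k <- which(rho <= thr)
    if (length(k)) k[1L] else max_lag
  }
  structure(max(1L, as.integer(tau)), method = method)
}

# histogram-based mutual information between x_t and x_{t+lag}
mutual_info_lag <- function(x, lag, bins = 16L) {
  n <- length(x) - lag
  a <- x[seq_len(n)]
  b <- x[seq_len(n) + lag]
  br <- seq(min(x), max(x), length.out = bins + 1L)
  ia <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(ia, ib) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' Delay-embed a scalar series
#'
#' Phase-space reconstruction by the method of delays: row i of the output
#' is `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`, giving
#' `n - (m-1)*tau` reconstructed points in m dimensions.
#'
#' @param x numeric series.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return object of class `neurodyn_embedding`: a numeric matrix
#'   (points x m) with attributes `m`, `tau`, `n`.
#' @export
#' @examples
#' delay_embed(1:4, m = 2, tau = 1)
delay_embed <- function(x, m, tau) {
  x <- as.numeric(x)
  m <- as.integer(m); tau <- as.integer(tau)
  stopifnot(m >= 1L, tau >= 1L)
  n <- length(x)
  np <- n - (m - 1L) * tau
  if (np < 2L)
    stop(sprintf("series of length %d too short for m = %d, tau = %d", n, m, tau))
  pts <- vapply(seq_len(m) - 1L, function(j) x[seq_len(np) + j * tau],
                numeric(np))
  if (np == 1L) pts <- matrix(pts, nrow = 1L)
  structure(pts, m = m, tau = tau, n = n, class = c("neurodyn_embedding", "matrix", "array"))
}

#' Select the embedding dimension by false nearest neighbors
#'
#' Kennel-style false-nearest-neighbor test: for each candidate dimension m,
#' the nearest neighbor of every point (outside a Theiler exclusion of
#' `tau`) is located in m dimensions and declared false if the extra
#' coordinate at dimension m+1 expands the distance by more than `r_tol`
#' times, or beyond `a_tol` times the series' standard deviation. The
#' smallest m whose false-neighbor fraction drops below `threshold` is
#' returned; stochastic series never saturate, in which case `max_m` is
#' returned with attribute `warning = TRUE`.
#'
#' @param x numeric series.
#' @param tau embedding delay.
#' @param max_m largest dimension tried (default 8).
#' @param method only `"false_nearest_neighbors"`.
#' @param threshold acceptable false-neighbor fraction (default 0.05).
#' @param r_tol,a_tol Kennel tolerances (defaults 10 and 2).
#' @return integer dimension with attributes `fnn` (fraction per m) and
#'   `warning`.
#' @export
select_embedding_dim <- function(x, tau, max_m = 8L,
                                 method = "false_nearest_neighbors",
                                 threshold = 0.05, r_tol = 10, a_tol = 2) {
  method <- match.arg(method, "false_nearest_neighbors")
  x <- as.numeric(x)
  tau <- as.integer(tau)
  sdx <- stats::sd(x)
  if (sdx == 0) stop("constant series")
  fnn <- rep(NA_real_, max_m)
  for (m in seq_len(max_m)) {
    np1 <- length(x) - m * tau          # points with an (m+1)-th coordinate
    if (np1 < 10L) stop("series too short for requested max_m at this tau")
    emb <- delay_embed(x, m, tau)[seq_len(np1), , drop = FALSE]
    nxt <- x[seq_len(np1) + m * tau]
    dm <- as.matrix(stats::dist(emb))
    diag(dm) <- Inf
    if (tau >= 1L) {                    # Theiler exclusion around each index
      for (k in seq_len(min(tau, np1 - 1L))) {
        idx <- seq_len(np1 - k)
        dm[cbind(idx, idx + k)] <- Inf
        dm[cbind(idx + k, idx)] <- Inf
      }
    }
    nn <- max.col(-dm, ties.method = "first")
    dnn <- dm[cbind(seq_len(np1), nn)]
    # neighbors at duplicate/floating-point-noise distance are exact
    # recurrences, not candidates for the false-neighbor ratio
    ok <- is.finite(dnn) & dnn > 1e-8 * sdx
    extra <- abs(nxt - nxt[nn])
    false_nb <- (extra / dnn > r_tol) | (sqrt(dnn^2 + extra^2) / sdx > a_tol)
    fnn[m] <- if (any(ok)) mean(false_nb[ok]) else 0
    if (fnn[m] < threshold)
      return(structure(m, fnn = fnn[seq_len(m)], warning = FALSE))
  }
  structure(as.integer(max_m), fnn = fnn, warning = TRUE)
}

#' Build a recurrence matrix from an embedded trajectory
#'
#' Entry (i, j) is 1 when the distance between embedded points i and j is at
#' most epsilon. In fixed-recurrence-rate mode (`target_rr`), epsilon is set
#' to the empirical `target_rr`-quantile (inverse CDF) of the off-diagonal
#' pairwise distances (pairs with `|i - j| <= theiler` excluded from the
#' bookkeeping). Distances that are numerically equal to the quantile
#' (relative tolerance 1e-9) are treated as one tie class and included as a
#' whole, so floating-point jitter never splits mathematically identical
#' distances into an arbitrary scatter of recurrence points. For continuous
#' distance distributions the achieved off-diagonal density matches the
#' target to within the quantile granularity (±0.005 for >= 100 points);
#' for degenerate inputs whose distance distribution has atoms (e.g. a
#' sinusoid sampled at an exact integer number of samples per period, whose
#' embedding visits finitely many points) the achieved density is the
#' nearest attainable tie-class boundary at or above the target.
#'
#' @param traj a `neurodyn_embedding` (or plain points-by-dims matrix).
#' @param target_rr desired recurrence rate in (0, 1); exactly one of
#'   `target_rr`/`epsilon` must be given.
#' @param epsilon fixed distance threshold.
#' @param metric `"euclidean"` or `"maximum"`.
#' @param theiler Theiler window: pairs with `|i - j| <= theiler` are
#'   excluded from density bookkeeping (and from the quantile in fixed-RR
#'   mode). Default 0.
#' @return object of class `neurodyn_rp`: list with binary `matrix`,
#'   `epsilon`, `target_rr`, `achieved_rr`, `metric`, `theiler`.
#' @export
recurrence_matrix <- function(traj, target_rr = NULL, epsilon = NULL,
                              metric = c("euclidean", "maximum"),
                              theiler = 0L) {
  metric <- match.arg(metric)
  pts <- unclass(traj)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 1L)
  np <- nrow(pts)
  theiler <- as.integer(theiler)
  if (is.null(target_rr) + is.null(epsilon) != 1L)
    stop("give exactly one of `target_rr` or `epsilon`")
  dm <- as.matrix(stats::dist(pts, method = if (metric == "euclidean") "euclidean" else "maximum"))
  off <- abs(row(dm) - col(dm)) > theiler
  if (!is.null(target_rr)) {
    stopifnot(target_rr > 0, target_rr < 1)
    if (np < 10L) stop("fixed-RR mode needs >= 10 points")
    dd <- sort(dm[off])
    if (dd[length(dd)] == 0) {
      warning("all points identical: recurrence matrix is all ones")
      epsilon <- 0
    } else {
      epsilon <- dd[max(1L, ceiling(target_rr * length(dd)))]
    }
  }
  # include the whole tie class at the threshold (relative tol 1e-9)
  R <- (dm <= epsilon + 1e-9 * abs(epsilon)) * 1L
  achieved <- sum(R[off]) / sum(off)
  structure(list(matrix = R, epsilon = epsilon,
                 target_rr = if (is.null(target_rr)) NA_real_ else target_rr,
                 achieved_rr = achieved, metric = metric, theiler = theiler),
            class = "neurodyn_rp")
}

#' @export
print.neurodyn_rp <- function(x, ...) {
  cat(sprintf("<neurodyn_rp> %d x %d, eps = %.4g, RR = %.4f (theiler %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$epsilon, x$achieved_rr, x$theiler))
  invisible(x)
}

# run lengths of 1s in a binary vector; returns integer lengths (possibly empty)
runs_of_ones <- function(v) {
  if (!length(v)) return(integer(0))
  r <- rle(as.integer(v))
  r$lengths[r$values == 1L]
}

#' Line-structure histograms of a recurrence matrix
#'
#' Tallies maximal runs of recurrence points along diagonals (excluding the
#' line of identity and the Theiler band) and along columns, plus maximal
#' runs of non-recurrence points ("white" vertical lines, the recurrence
#' times). The Theiler band of the source matrix is zeroed before scanning,
#' so diagonal and vertical structures are counted on the same matrix that
#' density bookkeeping uses.
#'
#' @param R a `neurodyn_rp` (or plain binary matrix).
#' @param theiler Theiler half-width used when `R` is a plain matrix
#'   (ignored otherwise; `neurodyn_rp` carries its own).
#' @return list with integer-vector elements `diagonal`, `vertical`,
#'   `white_vertical`, each the multiset of maximal run lengths.
#' @export
line_histograms <- function(R, theiler = 0L) {
  if (inherits(R, "neurodyn_rp")) {
    theiler <- R$theiler
    R <- R$matrix
  }
  stopifnot(is.matrix(R))
  np <- nrow(R)
  theiler <- max(0L, as.integer(theiler))
  Rz <- R
  for (k in 0:min(theiler, np - 1L)) {   # zero LOI + Theiler band
    idx <- seq_len(np - k)
    Rz[cbind(idx, idx + k)] <- 0L
    Rz[cbind(idx + k, idx)] <- 0L
  }
  diag_lens <- integer(0)
  for (k in (theiler + 1L):(np - 1L)) {  # upper triangle diagonals, doubled by symmetry
    v <- Rz[cbind(seq_len(np - k), seq_len(np - k) + k)]
    diag_lens <- c(diag_lens, runs_of_ones(v))
  }
  diag_lens <- rep(diag_lens, each = 2L)
  vert_lens <- integer(0)
  white_lens <- integer(0)
  for (j in seq_len(np)) {
    col <- Rz[, j]
    vert_lens <- c(vert_lens, runs_of_ones(col))
    white_lens <- c(white_lens, runs_of_ones(1L - col))
  }
  list(diagonal = diag_lens, vertical = vert_lens, white_vertical = white_lens)
}

# Shannon entropy (natural log) of a multiset of line lengths
line_entropy <- function(lens) {
  if (!length(lens)) return(0)
  p <- table(lens) / length(lens)
  -sum(p * log(p))
}

#' Recurrence quantification measures
#'
#' The nine standard RQA measures from the line-length histograms of a
#' recurrence matrix: recurrence rate (RR), determinism (DET), laminarity
#' (LAM), mean/max diagonal line length (Lmean, Lmax), diagonal line-length
#' entropy (Lentr), trapping time (TT), vertical line-length entropy
#' (VertEnt) and the entropy of the white-vertical (recurrence-time)
#' distribution (AvgWhiteVertEnt). Diagonal and vertical statistics use
#' lines of length >= `lmin`; the white-vertical distribution uses all
#' recurrence times (>= 1). A measure whose histogram is empty at `lmin` is
#' returned as 0 and its name is listed in the `flags` attribute rather
#' than propagating NaN.
#'
#' @param R a `neurodyn_rp` from [recurrence_matrix()] (or binary matrix).
#' @param lmin minimal line length for diagonal/vertical statistics
#'   (default 2).
#' @param theiler Theiler half-width when `R` is a plain matrix.
#' @return named numeric vector of the nine measures with attribute `flags`.
#' @export
rqa_measures <- function(R, lmin = 2L, theiler = 0L) {
  rr <- NA_real_
  if (inherits(R, "neurodyn_rp")) {
    rr <- R$achieved_rr
    theiler <- R$theiler
    Rm <- R$matrix
  } else Rm <- R
  lmin <- as.integer(lmin)
  stopifnot(lmin >= 2L)
  hist <- line_histograms(R, theiler = theiler)
  np <- nrow(Rm)
  if (is.na(rr)) {
    off <- abs(row(Rm) - col(Rm)) > theiler
    rr <- sum(Rm[off]) / sum(off)
  }
  flags <- character(0)
  d <- hist$diagonal
  v <- hist$vertical
  w <- hist$white_vertical
  dk <- d[d >= lmin]
  vk <- v[v >= lmin]
  det <- if (sum(d)) sum(dk) / sum(d) else { flags <- c(flags, "DET"); 0 }
  lam <- if (sum(v)) sum(vk) / sum(v) else { flags <- c(flags, "LAM"); 0 }
  lmean <- if (length(dk)) mean(dk) else { flags <- c(flags, "Lmean"); 0 }
  lmax <- if (length(d)) max(d) else { flags <- c(flags, "Lmax"); 0 }
  lentr <- if (length(dk)) line_entropy(dk) else { flags <- c(flags, "Lentr"); 0 }
  tt <- if (length(vk)) mean(vk) else { flags <- c(flags, "TT"); 0 }
  ventr <- if (length(vk)) line_entropy(vk) else { flags <- c(flags, "VertEnt"); 0 }
  wentr <- if (length(w)) line_entropy(w) else { flags <- c(flags, "AvgWhiteVertEnt"); 0 }
  structure(c(RR = rr, DET = det, LAM = lam, Lmean = lmean, Lmax = lmax,
              Lentr = lentr, TT = tt, VertEnt = ventr, AvgWhiteVertEnt = wentr),
            flags = flags)
}
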