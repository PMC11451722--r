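#' Coarse-grain a series by non-overlapping window means
#'
#' The multiscale coarse-graining operator: output element j is the mean
#' of samples `[j*scale + 1, (j+1)*scale]`; a trailing remainder shorter than
#' `scale` is truncated, so the output length is `floor(n/scale)`. At dyadic
#' scales `2^k` the result equals the level-k Haar approximation coefficients
#' divided by `2^(k/2)` (see [dwt_decompose()]).
#'
#' @param x numeric series.
#' @param scale positive integer window length.
#' @return numeric vector of length `floor(length(x)/scale)`.
#' @export
#' @examples
#' coarse_grain(c(1, 3, 5, 7), 2)  # 2 6
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1L) stop("`scale` must be a positive integer")
  n <- length(x)
  if (n < 1L) stop("empty series")
  if (n < scale) stop("series shorter than `scale`")
  if (scale == 1L) return(as.numeric(x))
  m <- n %/% scale
  colMeans(matrix(x[seq_len(m * scale)], nrow = scale))
}

#' Orthonormal wavelet scaling filters
#'
#' Scaling (lowpass) coefficients for the supported orthonormal wavelets, in
#' standard order with `sum(h) = sqrt(2)`. Haar gives the coarse-graining
#' identity; the longer extremal-phase Daubechies filters trade time
#' localization for much sharper band selectivity.
#'
#' @param wavelet one of `"haar"`, `"db2"`, `"db4"`, `"db8"`.
#' @return numeric vector of filter coefficients.
#' @export
wavelet_filter <- function(wavelet = c("haar", "db2", "db4", "db8")) {
  wavelet <- match.arg(wavelet)
  switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(4.8296291314453416e-01, 8.3651630373780794e-01,
            2.2414386804201339e-01, -1.2940952255126037e-01),
    db4 = c(2.3037781330889651e-01, 7.1484657055291567e-01,
            6.3088076792985892e-01, -2.7983769416859854e-02,
            -1.8703481171909309e-01, 3.0841381835560764e-02,
            3.2883011666885197e-02, -1.0597401785069032e-02),
    db8 = c(5.4415842243104008e-02, 3.1287159091429995e-01,
            6.7563073629728976e-01, 5.8535468365420673e-01,
            -1.5829105256349306e-02, -2.8401554296154691e-01,
            4.7248457391328279e-04, 1.2874742662047847e-01,
            -1.7369301001807547e-02, -4.4088253930794755e-02,
            1.3981027917398282e-02, 8.7460940474057766e-03,
            -4.8703529934515741e-03, -3.9174037337694705e-04,
            6.7544940645056933e-04, -1.1747678412476953e-04))
}

# quadrature mirror highpass from a scaling filter
qmf <- function(h) (-1)^(seq_along(h) - 1L) * rev(h)

# one periodic analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, h) {
  n <- length(x)
  g <- qmf(h)
  idx0 <- seq(0L, n - 2L, by = 2L)
  a <- numeric(n / 2L)
  d <- numeric(n / 2L)
  for (i in seq_along(h)) {
    xi <- x[((idx0 + i - 1L) %% n) + 1L]
    a <- a + h[i] * xi
    d <- d + g[i] * xi
  }
  list(approx = a, detail = d)
}

# one periodic synthesis step (inverse of dwt_step)
dwt_unstep <- function(approx, detail, h) {
  n <- 2L * length(approx)
  g <- qmf(h)
  out <- numeric(n)
  idx0 <- seq(0L, n - 2L, by = 2L)
  for (i in seq_along(h)) {
    pos <- ((idx0 + i - 1L) %% n) + 1L
    out[pos] <- out[pos] + h[i] * approx + g[i] * detail
  }
  out
}

#' Discrete wavelet decomposition into detail and approximation coefficients
#'
#' Multi-level orthonormal DWT with periodic boundary handling. Detail level
#' j nominally spans the frequency band `(fs/2^(j+1), fs/2^j]`; the
#' level-`levels` approximation holds everything below the last detail band.
#' The transform is orthogonal, so [dwt_reconstruct()] restores the input
#' exactly (to floating point) and energy is conserved across coefficients.
#' Input whose length is not a multiple of `2^levels` is zero-padded
#' internally; the padded length is recorded and stripped on reconstruction.
#'
#' @param x numeric series with `length(x) >= 2^levels`.
#' @param levels number of decomposition levels (>= 1).
#' @param wavelet wavelet name, see [wavelet_filter()]. Default `"haar"`,
#'   whose approximation coefficients equal coarse-grained means times
#'   `2^(level/2)`.
#' @return a list of class `neurodyn_dwt` with `approx` (coarsest
#'   approximation coefficients), `details` (list, level 1 = finest),
#'   `levels`, `n` (original length), `n_pad`, `wavelet`.
#' @seealso [coarse_grain()], [to_band_signals()]
#' @export
dwt_decompose <- function(x, levels, wavelet = "haar") {
  h <- wavelet_filter(wavelet)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  n <- length(x)
  if (n < 2^levels)
    stop(sprintf("series of length %d too short for %d levels", n, levels))
  block <- 2^levels
  n_pad <- ((n + block - 1L) %/% block) * block
  xp <- c(as.numeric(x), numeric(n_pad - n))
  details <- vector("list", levels)
  a <- xp
  for (j in seq_len(levels)) {
    st <- dwt_step(a, h)
    details[[j]] <- st$detail
    a <- st$approx
  }
  structure(list(approx = a, details = details, levels = levels,
                 n = n, n_pad = n_pad, wavelet = wavelet),
            class = "neurodyn_dwt")
}

#' Invert a wavelet decomposition
#'
#' @param d a `neurodyn_dwt` from [dwt_decompose()].
#' @param keep optional: either `"approx"` or a detail level number; all
#'   other coefficient sets are zeroed before synthesis, yielding the
#'   full-length band-limited component for that level.
#' @return numeric vector of the original length.
#' @export
dwt_reconstruct <- function(d, keep = NULL) {
  stopifnot(inherits(d, "neurodyn_dwt"))
  h <- wavelet_filter(d$wavelet)
  a <- d$approx
  details <- d$details
  if (!is.null(keep)) {
    if (identical(keep, "approx")) {
      details <- lapply(details, function(v) numeric(length(v)))
    } else {
      keep <- as.integer(keep)
      stopifnot(keep >= 1L, keep <= d$levels)
      a <- numeric(length(a))
      for (j in seq_along(details))
        if (j != keep) details[[j]] <- numeric(length(details[[j]]))
    }
  }
  for (j in rev(seq_len(d$levels))) a <- dwt_unstep(a, details[[j]], h)
  a[seq_len(d$n)]
}

#' Clinical band names for a dyadic filter bank
#'
#' Assigns each dyadic detail band `(fs/2^(j+1), fs/2^j]` the clinical EEG
#' band name (delta, theta, alpha, beta, gamma) with which it overlaps most;
#' bands mapping to the same clinical name are disambiguated with a numeric
#' suffix, highest-frequency first (e.g. `gamma2`, `gamma1`).
#'
#' @param fs sampling rate in Hz.
#' @param n_bands number of detail bands.
#' @return character vector of band names, finest (highest-frequency) first.
#' @export
band_names_for <- function(fs, n_bands) {
  clinical <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                   beta = c(13, 30), gamma = c(30, 100))
  hi <- fs / 2^(seq_len(n_bands))
  lo <- fs / 2^(seq_len(n_bands) + 1L)
  base <- vapply(seq_len(n_bands), function(j) {
    ov <- vapply(clinical, function(cb)
      max(0, min(hi[j], cb[2]) - max(lo[j], cb[1])), numeric(1))
    names(clinical)[which.max(ov)]
  }, character(1))
  out <- base
  for (nm in unique(base)) {
    idx <- which(base == nm)
    if (length(idx) > 1L)  # finest first -> highest suffix
      out[idx] <- paste0(nm, rev(seq_along(idx)))
  }
  out
}

#' Decompose a channel into named frequency-band series
#'
#' Splits a series into `n_bands` dyadic frequency bands by wavelet details,
#' each reconstructed back to the full time resolution so that all band
#' series share the original sampling grid (recurrence and entropy measures
#' downstream require equal-length series). Band `j` spans
#' `(fs/2^(j+1), fs/2^j]` Hz; names follow the clinical convention via
#' [band_names_for()]. The residual approximation (below the lowest band) is
#' returned separately, and the band series plus residual sum exactly to the
#' input. The default `db8` filter keeps >90 percent of a mid-band
#' sinusoid's energy inside its nominal band; pass `wavelet = "haar"` for
#' the coarse-graining-equivalent bank.
#'
#' @param x numeric series (or single-channel [recording()]).
#' @param fs sampling rate in Hz (ignored if `x` is a recording).
#' @param n_bands number of bands (default 6).
#' @param method `"wavelet_details"` (the only implemented path; named for
#'   forward compatibility with coarse-grain-difference banks).
#' @param wavelet wavelet name, see [wavelet_filter()].
#' @param include_approx if `TRUE`, append the residual approximation as an
#'   extra lowest band named `"slow"` (an alternative convention for the
#'   lowest band; default `FALSE`).
#' @return list of class `neurodyn_bands`: `bands` (named list of full-length
#'   series), `ranges` (named list of `c(lo, hi)` Hz), `approx` (residual
#'   series), `fs`, `method`, `wavelet`.
#' @export
#' @examples
#' r <- generate_system("sine", 1024, params = list(frequency = 10), fs = 250)
#' b <- to_band_signals(r, fs = 250)
#' names(b$bands)
to_band_signals <- function(x, fs, n_bands = 6L, method = "wavelet_details",
                            wavelet = "db8", include_approx = FALSE) {
  if (inherits(x, "neurodyn_recording")) {
    if (n_channels(x) != 1L) stop("pass one channel at a time")
    fs <- x$fs
    x <- x$data[1L, ]
  }
  method <- match.arg(method, "wavelet_details")
  n_bands <- as.integer(n_bands)
  stopifnot(n_bands >= 1L)
  floor_hz <- fs / 2^(n_bands + 1L)
  if (floor_hz < 0.25)
    stop(sprintf("lowest band floor %.3g Hz below resolvable limit for fs = %g",
                 floor_hz, fs))
  d <- dwt_decompose(x, levels = n_bands, wavelet = wavelet)
  nms <- band_names_for(fs, n_bands)
  bands <- stats::setNames(
    lapply(seq_len(n_bands), function(j) dwt_reconstruct(d, keep = j)), nms)
  ranges <- stats::setNames(
    lapply(seq_len(n_bands), function(j) c(fs / 2^(j + 1L), fs / 2^j)), nms)
  approx <- dwt_reconstruct(d, keep = "approx")
  if (include_approx) {
    bands$slow <- approx
    ranges$slow <- c(0, fs / 2^(n_bands + 1L))
  }
  structure(list(bands = bands, ranges = ranges, approx = approx,
                 fs = fs, method = method, wavelet = wavelet),
            class = "neurodyn_bands")
}

#' Mean power of a series
#'
#' Power as the mean of the squared amplitude over the interval: for a
#' unit-amplitude sinusoid over whole periods this is 0.5; for zero-mean
#' noise it estimates the variance.
#'
#' @param x non-empty numeric series.
#' @return scalar mean squared amplitude.
#' @export
band_power <- function(x) {
  if (!length(x)) stop("empty series")
  mean(as.numeric(x)^2)
}
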