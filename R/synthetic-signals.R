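#' Generate canonical dynamical systems and stochastic processes
#'
#' Produces test signals with known dynamical properties: the Lorenz system
#' (chaotic flow), the logistic map (chaotic map), a pure sinusoid (periodic),
#' and the stochastic processes white noise, pink (1/f) noise, Brownian
#' motion and fractional Gaussian noise. These are the ground-truth inputs
#' for every downstream stage: a sinusoid has determinism 1, the fully
#' chaotic logistic map has Lyapunov exponent ln 2, fGn has a prescribed
#' Hurst exponent, and so on.
#'
#' Deterministic systems are bit-reproducible given the same initial state;
#' the Lorenz equations are integrated with fixed-step fourth-order
#' Runge-Kutta (dt as given, default 0.01) and the first `transient` steps
#' are discarded so that sampling starts on the attractor. Stochastic kinds
#' require a `seed`.
#'
#' @param name one of `"lorenz"`, `"logistic"`, `"sine"`, `"white_noise"`,
#'   `"pink_noise"`, `"brownian"`, `"fgn"`.
#' @param n_samples number of samples to return per state variable (>= 2).
#' @param params named list of system parameters: `sigma`, `rho`, `beta` for
#'   Lorenz; `r` for the logistic map; `frequency` (Hz), `amplitude`, `phase`
#'   for the sinusoid; `sd` for white noise; `hurst` for fGn.
#' @param fs sampling rate in Hz attached to the output (for maps and noise
#'   this is nominal; default 1). For `"sine"` it defines the time axis.
#' @param dt integration step for Lorenz (default 0.01 s; the recording `fs`
#'   is then `1/dt`).
#' @param initial_state numeric vector of initial conditions (length 3 for
#'   Lorenz, 1 for the logistic map). Defaults: Lorenz `c(1, 1, 1)`,
#'   logistic `0.3`.
#' @param seed integer seed, required for the stochastic kinds.
#' @param transient number of initial Lorenz integration steps to discard
#'   (default 1000).
#' @return a [recording()]; Lorenz yields three channels `x`, `y`, `z`,
#'   everything else one channel.
#' @export
#' @examples
#' generate_system("logistic", 5, params = list(r = 4), initial_state = 0.3)
#' generate_system("sine", 100, params = list(frequency = 10), fs = 250)
generate_system <- function(name, n_samples,
                            params = list(), fs = NULL, dt = NULL,
                            initial_state = NULL, seed = NULL,
                            transient = 1000L) {
  name <- match.arg(name, c("lorenz", "logistic", "sine", "white_noise",
                            "pink_noise", "brownian", "fgn"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) stop("`n_samples` must be >= 2")
  if (length(params) && any(!vapply(params, function(p) all(is.finite(p)), TRUE)))
    stop("all `params` must be finite")
  stochastic <- name %in% c("white_noise", "pink_noise", "brownian", "fgn")
  if (stochastic && is.null(seed))
    stop(sprintf("stochastic system '%s' requires a `seed` for reproducibility", name))

  switch(name,
    lorenz = {
      if (is.null(dt)) dt <- 0.01
      p <- modifyList(list(sigma = 10, rho = 28, beta = 8 / 3), params)
      x0 <- if (is.null(initial_state)) c(1, 1, 1) else initial_state
      stopifnot(length(x0) == 3L)
      xyz <- lorenz_rk4(x0, p$sigma, p$rho, p$beta, dt,
                        n_samples + as.integer(transient))
      xyz <- xyz[(as.integer(transient) + 1L):(as.integer(transient) + n_samples), , drop = FALSE]
      recording(t(xyz), fs = 1 / dt, labels = c("x", "y", "z"),
                meta = list(system = "lorenz", params = p, dt = dt,
                            scheme = "fixed-step RK4", transient = transient,
                            initial_state = x0))
    },
    logistic = {
      p <- modifyList(list(r = 4), params)
      x0 <- if (is.null(initial_state)) 0.3 else initial_state[1L]
      x <- numeric(n_samples)
      x[1L] <- x0
      for (i in seq_len(n_samples - 1L)) x[i + 1L] <- p$r * x[i] * (1 - x[i])
      recording(x, fs = if (is.null(fs)) 1 else fs, labels = "x",
                meta = list(system = "logistic", params = p, initial_state = x0))
    },
    sine = {
      if (is.null(fs)) stop("`fs` is required for the sinusoid")
      p <- modifyList(list(frequency = 10, amplitude = 1, phase = 0), params)
      t_ <- (seq_len(n_samples) - 1L) / fs
      x <- p$amplitude * sin(2 * pi * p$frequency * t_ + p$phase)
      recording(x, fs = fs, labels = "x",
                meta = list(system = "sine", params = p))
    },
    white_noise = {
      p <- modifyList(list(sd = 1), params)
      x <- with_seed(seed, stats::rnorm(n_samples, sd = p$sd))
      recording(x, fs = if (is.null(fs)) 1 else fs, labels = "x",
                meta = list(system = "white_noise", params = p, seed = seed))
    },
    pink_noise = {
      x <- with_seed(seed, pink_noise_fft(n_samples))
      recording(x, fs = if (is.null(fs)) 1 else fs, labels = "x",
                meta = list(system = "pink_noise", method = "spectral 1/f shaping",
                            seed = seed))
    },
    brownian = {
      x <- with_seed(seed, cumsum(stats::rnorm(n_samples)))
      recording(x, fs = if (is.null(fs)) 1 else fs, labels = "x",
                meta = list(system = "brownian", seed = seed))
    },
    fgn = {
      p <- modifyList(list(hurst = 0.7), params)
      x <- generate_fgn(p$hurst, n_samples, seed)
      meta <- attr(x, "meta")
      recording(as.numeric(x), fs = if (is.null(fs)) 1 else fs, labels = "x",
                meta = meta)
    }
  )
}

# Fixed-step RK4 integration of the Lorenz equations; returns steps x 3.
lorenz_rk4 <- function(x0, sigma, rho, beta, dt, n_steps) {
  f <- function(s) c(sigma * (s[2L] - s[1L]),
                     s[1L] * (rho - s[3L]) - s[2L],
                     s[1L] * s[2L] - beta * s[3L])
  out <- matrix(0, nrow = n_steps, ncol = 3L)
  s <- as.numeric(x0)
  for (i in seq_len(n_steps)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i, ] <- s
  }
  out
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 1/f-amplitude noise by spectral shaping of white Gaussian noise,
# normalized to unit variance. Uses the RNG in its current state.
pink_noise_fft <- function(n) {
  m <- 2L * n
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  freq <- c(1, seq_len(m - 1L))            # guard DC
  scale <- 1 / sqrt(pmin(freq, m - freq + 1))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

#' Generate fractional Gaussian noise
#'
#' Exact synthesis of zero-mean, unit-variance fractional Gaussian noise
#' (the increment process of fractional Brownian motion) with Hurst
#' exponent `hurst`, by circulant embedding of the fGn autocovariance
#' (Davies-Harte spectral method). `hurst = 0.5` reduces to white noise;
#' `hurst > 0.5` gives long-range positive autocorrelation.
#'
#' @param hurst target Hurst exponent, strictly in (0, 1).
#' @param n number of samples.
#' @param seed integer seed (required; the generator is fully reproducible).
#' @return numeric vector of length `n` with a `meta` attribute recording the
#'   method and parameters.
#' @export
#' @examples
#' x <- generate_fgn(0.8, 1024, seed = 1)
#' stats::sd(x)
generate_fgn <- function(hurst, n, seed) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly in (0, 1)")
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  n <- as.integer(n)
  stopifnot(n >= 2L)
  # fGn autocovariance gamma(k) = .5 (|k+1|^2H - 2|k|^2H + |k-1|^2H)
  k <- 0:n
  gamma <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                    abs(k - 1)^(2 * hurst))
  # circulant first row of length 2n: gamma(0..n), gamma(n-1..1)
  row <- c(gamma, rev(gamma[2:n]))
  lambda <- Re(stats::fft(row))
  # small negative eigenvalues can arise from rounding; clip at 0
  lambda[lambda < 0] <- 0
  m <- length(row)
  z <- with_seed(seed, {
    zr <- stats::rnorm(m)
    zi <- stats::rnorm(m)
    complex(real = zr, imaginary = zi)
  })
  # with coefficients sqrt(lambda_k / m) the real part has covariance
  # Cov(x_j, x_l) = sum_k (lambda_k/m) cos(2 pi (j-l) k / m) = gamma(j-l)
  x <- Re(stats::fft(sqrt(lambda / m) * z, inverse = TRUE))[seq_len(n)]
  structure(x, meta = list(system = "fgn", method = "circulant embedding (Davies-Harte)",
                           hurst = hurst, seed = seed))
}
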