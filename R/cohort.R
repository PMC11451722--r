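#' Default age-effect model for the synthetic cohort
#'
#' Per-band coefficients of the cohort signal model. For each band the
#' oscillation weight is `power[1] + power[2] * a` and the noise-mixing
#' (complexity) fraction is `complexity[1] + complexity[2] * a`, where `a`
#' is age scaled to \[0, 1\] over the cohort age range. The defaults follow
#' the canonical developmental EEG picture: faster rhythms (alpha/beta)
#' strengthen with age while slow (theta/delta) activity recedes, and
#' signal complexity rises as circuits mature.
#'
#' @param fs,n_bands band layout; names must match [band_names_for()].
#' @return named list of per-band `list(power = c(base, slope),
#'   complexity = c(base, slope))`.
#' @export
default_effect_model <- function(fs = 64, n_bands = 6L) {
  nms <- band_names_for(fs, n_bands)
  power_tab <- list(gamma = c(0.4, 0.6), beta = c(0.4, 0.8),
                    alpha = c(0.5, 1.0), theta = c(1.2, -0.7),
                    delta = c(1.4, -0.9))
  out <- lapply(nms, function(nm) {
    base <- sub("[0-9]+$", "", nm)
    pw <- power_tab[[base]]
    if (is.null(pw)) pw <- c(0.8, 0)
    list(power = pw, complexity = c(0.25, 0.5))
  })
  stats::setNames(out, nms)
}

#' Generate an age-modulated synthetic EEG cohort
#'
#' Builds `n_subjects` multichannel recordings whose band-wise power and
#' complexity vary monotonically with a latent "age" variable, emulating a
#' developmental cohort: each channel is a sum over bands of
#' `w_b(age) * [(1 - c_b(age)) * oscillation_b + c_b(age) * bandnoise_b]`
#' plus broadband measurement noise, where `w_b` and `c_b` follow
#' `effect_model`. Ages sit on a uniform grid over `age_range` so
#' correlation targets are stable across seeds. A single `noise_sd` knob
#' scales every nuisance source: white measurement noise, per-subject-band
#' lognormal weight jitter, a shared per-subject complexity offset, and a
#' global per-subject amplitude factor (the latter two create the dominant
#' non-age variance that unsupervised factorization tends to latch onto).
#' With `noise_sd = 0` the designed band statistics are strictly monotone
#' in age.
#'
#' All randomness derives from `seed` through an independent per-subject
#' stream, so any subject subset reproduces identically.
#'
#' @param n_subjects number of subjects (default 40).
#' @param n_channels channels per recording, drawn in order from
#'   [montage_10_20()] unless `channels` is given (default 4:
#'   F3, F4, O1, O2).
#' @param fs sampling rate in Hz (default 64).
#' @param duration recording length in seconds (default 4).
#' @param age_range age span in months (default 6-84).
#' @param effect_model see [default_effect_model()].
#' @param noise_sd master nuisance scale (default 0.5).
#' @param seed integer seed (required).
#' @param channels optional explicit channel label vector.
#' @return list with `recordings` (named list of [recording()]) and
#'   `cohort` (data.frame: `subject_id`, `age_months`, `sex`).
#' @export
generate_cohort <- function(n_subjects = 40L, n_channels = 4L, fs = 64,
                            duration = 4, age_range = c(6, 84),
                            effect_model = NULL, noise_sd = 0.5,
                            seed, channels = NULL) {
  if (missing(seed)) stop("`seed` is required")
  n_subjects <- as.integer(n_subjects)
  n <- as.integer(round(fs * duration))
  if (is.null(channels)) {
    montage <- c("F3", "F4", "O1", "O2",
                 setdiff(montage_10_20(), c("F3", "F4", "O1", "O2")))
    if (n_channels > length(montage))
      stop("n_channels exceeds the 10-20 montage; pass `channels` explicitly")
    channels <- montage[seq_len(n_channels)]
  }
  n_bands <- 6L
  if (is.null(effect_model)) effect_model <- default_effect_model(fs, n_bands)
  bnames <- names(effect_model)
  centers <- vapply(seq_along(bnames), function(j)
    0.75 * fs / 2^(j + 1L), numeric(1)) * 2    # geometric-ish band centers
  # fixed spatial gains: alpha posterior-dominant, beta frontal-dominant
  gain <- matrix(1, nrow = length(channels), ncol = n_bands,
                 dimnames = list(channels, bnames))
  post <- grepl("^(O|P|T[56])", channels)
  front <- grepl("^(F|Fp)", channels)
  gain[post, grep("^alpha", bnames)] <- 1.3
  gain[front, grep("^beta", bnames)] <- 1.2

  ages <- seq(age_range[1], age_range[2], length.out = n_subjects)
  sex <- rep(c("F", "M"), length.out = n_subjects)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  t_ <- (seq_len(n) - 1L) / fs

  recs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sseed <- (as.integer(seed) %% 100000L) * 10007L + s * 7919L
    rec <- with_seed(sseed, {
      a <- (ages[s] - age_range[1]) / diff(age_range)
      g_cplx <- stats::rnorm(1, 0, 0.25 * noise_sd)      # shared complexity shift
      amp <- exp(stats::rnorm(1, 0, 0.5 * noise_sd))     # global amplitude
      dat <- matrix(0, nrow = length(channels), ncol = n)
      for (ch in seq_along(channels)) {
        sig <- numeric(n)
        for (b in seq_len(n_bands)) {
          em <- effect_model[[b]]
          w <- max(0.05, em$power[1] + em$power[2] * a) * gain[ch, b]
          w <- w * exp(stats::rnorm(1, 0, 0.1 * noise_sd))
          cx <- min(0.95, max(0.05, em$complexity[1] + em$complexity[2] * a + g_cplx))
          osc <- sin(2 * pi * centers[b] * t_ + stats::runif(1, 0, 2 * pi))
          bn <- band_component_noise(n, b, fs)
          comp <- (1 - cx) * osc / stats::sd(osc) + cx * bn
          sig <- sig + w * comp / stats::sd(comp)
        }
        sig <- sig + 0.15 * noise_sd * stats::rnorm(n)
        dat[ch, ] <- amp * sig
      }
      recording(dat, fs = fs, labels = channels,
                meta = list(subject_id = ids[s], age_months = ages[s],
                            seed = sseed, noise_sd = noise_sd))
    })
    recs[[s]] <- rec
  }
  names(recs) <- ids
  list(recordings = recs,
       cohort = data.frame(subject_id = ids, age_months = ages, sex = sex,
                           stringsAsFactors = FALSE))
}

# unit-SD noise confined to dyadic band `b` of `n_bands`; uses current RNG
band_component_noise <- function(n, b, fs, n_bands = 6L) {
  w <- stats::rnorm(n)
  d <- dwt_decompose(w, levels = n_bands, wavelet = "db8")
  x <- dwt_reconstruct(d, keep = b)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}
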