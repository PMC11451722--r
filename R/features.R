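#' Feature-extraction configuration
#'
#' Bundles every tunable of the per-recording measure pipeline with
#' field-standard defaults: 6 dyadic wavelet bands, delay embedding with
#' m = 3 and the first-autocorrelation-zero delay, fixed recurrence rate
#' 0.05 with minimal line length 2 and Theiler window equal to the delay,
#' entropy templates m = 2 at r = 0.2 band SD, and the 15-measure set
#' (Power, the nine recurrence measures, sample entropy, correlation
#' dimension, DFA, Hurst, Lyapunov). Approximate and permutation entropy
#' are available by adding `"ApEn"`/`"PermEn"` to `measures`.
#'
#' @param n_bands number of frequency bands.
#' @param wavelet band-splitting wavelet (see [wavelet_filter()]).
#' @param measures character vector of measure names.
#' @param embed_m embedding dimension for recurrence/D2/Lyapunov.
#' @param delay_method delay selector method (see [select_delay()]).
#' @param target_rr fixed recurrence rate.
#' @param lmin minimal line length.
#' @param entropy_m,entropy_r sample/approximate entropy template length and
#'   tolerance (fraction of band SD).
#' @param perm_order permutation-entropy order.
#' @param max_points cap on embedded points entering the quadratic-cost
#'   measures (longer series use the leading window; default 1500).
#' @param min_length band series shorter than this have all measures
#'   flagged (default 64).
#' @return named list of class `neurodyn_config`.
#' @export
feature_config <- function(n_bands = 6L, wavelet = "db8",
                           measures = c("Power", "RR", "DET", "LAM", "Lmean",
                                        "Lmax", "Lentr", "TT", "VertEnt",
                                        "AvgWhiteVertEnt", "SampEn", "D2",
                                        "DFA", "Hurst", "Lyapunov"),
                           embed_m = 3L, delay_method = "autocorr_zero",
                           target_rr = 0.05, lmin = 2L,
                           entropy_m = 2L, entropy_r = 0.2,
                           perm_order = 3L, max_points = 1500L,
                           min_length = 64L) {
  known <- c("Power", "RR", "DET", "LAM", "Lmean", "Lmax", "Lentr", "TT",
             "VertEnt", "AvgWhiteVertEnt", "SampEn", "ApEn", "PermEn",
             "D2", "DFA", "Hurst", "Lyapunov")
  bad <- setdiff(measures, known)
  if (length(bad))
    stop("unknown measure name(s): ", paste(bad, collapse = ", "))
  structure(list(n_bands = as.integer(n_bands), wavelet = wavelet,
                 measures = measures, embed_m = as.integer(embed_m),
                 delay_method = delay_method, target_rr = target_rr,
                 lmin = as.integer(lmin), entropy_m = as.integer(entropy_m),
                 entropy_r = entropy_r, perm_order = as.integer(perm_order),
                 max_points = as.integer(max_points),
                 min_length = as.integer(min_length)),
            class = "neurodyn_config")
}

rqa_names <- function() c("RR", "DET", "LAM", "Lmean", "Lmax", "Lentr", "TT",
                          "VertEnt", "AvgWhiteVertEnt")

# all configured measures for one band series; returns list(values, flags)
band_measures <- function(x, fs, config) {
  meas <- config$measures
  vals <- stats::setNames(numeric(length(meas)), meas)
  flags <- character(0)
  flag_all <- function(reason) {
    list(values = vals, flags = meas)
  }
  x <- as.numeric(x)
  if (length(x) < config$min_length || stats::sd(x) == 0 || !all(is.finite(x)))
    return(flag_all("degenerate series"))

  grab <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) structure(0, flag = conditionMessage(e)))
    if (!is.null(attr(v, "flag"))) flags <<- c(flags, name)
    vals[name] <<- as.numeric(v)
  }

  if ("Power" %in% meas) grab("Power", band_power(x))
  need_embed <- any(c(rqa_names(), "D2", "Lyapunov") %in% meas)
  if (need_embed) {
    tau <- tryCatch(as.integer(select_delay(x, config$delay_method)),
                    error = function(e) 1L)
    # keep enough points for quadratic-cost measures
    max_tau <- max(1L, (length(x) - 50L) %/% max(1L, config$embed_m - 1L))
    tau <- min(tau, max_tau)
    emb <- delay_embed(x, config$embed_m, tau)
    if (nrow(emb) > config$max_points) {
      at <- attributes(emb)
      emb <- emb[seq_len(config$max_points), , drop = FALSE]
      attributes(emb) <- modifyList(at, list(dim = dim(emb)))
    }
    if (any(rqa_names() %in% meas)) {
      rp <- tryCatch(recurrence_matrix(emb, target_rr = config$target_rr,
                                       theiler = tau),
                     error = function(e) NULL)
      if (is.null(rp)) {
        flags <- c(flags, intersect(rqa_names(), meas))
      } else {
        rq <- rqa_measures(rp, lmin = config$lmin)
        for (nm in intersect(rqa_names(), meas)) vals[nm] <- rq[[nm]]
        flags <- c(flags, intersect(attr(rq, "flags"), meas))
      }
    }
    if ("D2" %in% meas)
      grab("D2", correlation_dimension(emb, theiler = tau))
    if ("Lyapunov" %in% meas)
      grab("Lyapunov", lyapunov_max(emb, fs = fs))
  }
  if ("SampEn" %in% meas)
    grab("SampEn", sample_entropy(x[seq_len(min(length(x), config$max_points))],
                                  m = config$entropy_m, r = config$entropy_r))
  if ("ApEn" %in% meas)
    grab("ApEn", entropy_variants(x[seq_len(min(length(x), config$max_points))],
                                  "approximate", m = config$entropy_m,
                                  r = config$entropy_r))
  if ("PermEn" %in% meas)
    grab("PermEn", entropy_variants(x, "permutation", order = config$perm_order))
  if ("DFA" %in% meas) grab("DFA", dfa(x))
  if ("Hurst" %in% meas) grab("Hurst", hurst_exponent(x))
  list(values = vals, flags = unique(flags))
}

#' Extract the dynamical measure table of a recording
#'
#' Computes every configured measure for every (channel, band) pair of a
#' recording: each channel is split into frequency bands
#' ([to_band_signals()]) and each band series is summarized by the measure
#' set of the configuration. Failures (too-short or constant band series,
#' empty line histograms, missing scaling regions) yield flagged
#' placeholder zeros, never missing values; the `flags` column lists the
#' affected measure names.
#'
#' @param rec a [recording()].
#' @param config a [feature_config()].
#' @return data.frame with columns `channel`, `band`, one column per
#'   measure, and `flags` (semicolon-joined flagged measure names, `""` if
#'   clean). `channels x bands` rows, `channels x bands x measures` measure
#'   values.
#' @export
#' @examples
#' rec <- generate_system("white_noise", 512, fs = 128, seed = 1)
#' f <- extract_features(rec, feature_config(measures = c("Power", "SampEn"),
#'                                           n_bands = 4))
#' dim(f)
extract_features <- function(rec, config = feature_config()) {
  stopifnot(inherits(rec, "neurodyn_recording"))
  rows <- vector("list", n_channels(rec) * config$n_bands)
  i <- 0L
  for (ch in seq_len(n_channels(rec))) {
    bs <- to_band_signals(rec$data[ch, ], fs = rec$fs,
                          n_bands = config$n_bands, wavelet = config$wavelet)
    for (b in names(bs$bands)) {
      i <- i + 1L
      bm <- band_measures(bs$bands[[b]], fs = rec$fs, config = config)
      rows[[i]] <- data.frame(channel = rec$labels[ch], band = b,
                              t(bm$values),
                              flags = paste(bm$flags, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
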