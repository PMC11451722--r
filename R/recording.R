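#' Multichannel recording container
#'
#' A `neurodyn_recording` holds a channels-by-samples numeric matrix together
#' with its sampling rate, channel labels and free-form metadata. All
#' downstream stages (band decomposition, feature extraction, the pipeline)
#' consume this container, whether the data came from a file or from the
#' synthetic generators.
#'
#' @param data numeric matrix, channels in rows, samples in columns. A bare
#'   numeric vector is promoted to a single-channel matrix.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of channel labels; defaults to
#'   `ch1, ch2, ...`.
#' @param meta named list of provenance metadata (generator name, parameters,
#'   integration scheme, seed, ...).
#' @return an object of class `neurodyn_recording` with elements `data`,
#'   `fs`, `labels`, `meta`.
#' @export
#' @examples
#' r <- recording(matrix(rnorm(200), nrow = 2), fs = 100)
#' n_channels(r)
#' n_samples(r)
recording <- function(data, fs, labels = NULL, meta = list()) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("`labels` length must equal the number of channels")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, meta = meta),
    class = "neurodyn_recording"
  )
}

#' @rdname recording
#' @param x a `neurodyn_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @export
print.neurodyn_recording <- function(x, ...) {
  cat(sprintf(
    "<neurodyn_recording> %d channel(s) x %d samples @ %g Hz (%.3g s)\n",
    n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs
  ))
  cat("  labels:", paste(utils::head(x$labels, 8L), collapse = ", "),
      if (n_channels(x) > 8L) "..." else "", "\n")
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Standard 10-20 scalp montage labels
#'
#' The 19 electrode labels of the international 10-20 system, in the
#' conventional anterior-to-posterior order. The synthetic cohort generator
#' draws its channel labels from this set.
#'
#' @return character vector of length 19.
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}
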