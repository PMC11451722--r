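#' Read a multichannel recording from disk
#'
#' Two formats are supported. `"csv"`: comma-separated, header row of
#' channel labels, first column the time axis in seconds (the format
#' written by [write_recording_csv()]); the sampling rate is recovered
#' from the time column. `"edf"`: European Data Format, read directly from
#' the binary header and 16-bit records; an `EDF Annotations` signal is
#' skipped, and all remaining signals must share one sampling rate.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_recording_csv(path) else read_recording_edf(path)
}

read_recording_csv <- function(path) {
  tb <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tb) < 2L) stop("recording CSV needs a time column plus channels")
  t_ <- tb[[1L]]
  dt <- diff(t_)
  if (length(dt) < 1L || any(dt <= 0)) stop("time column is not increasing")
  fs <- 1 / stats::median(dt)
  labels <- names(tb)[-1L]
  dat <- t(as.matrix(tb[, -1L, drop = FALSE]))
  if (anyNA(dat)) {
    bad <- labels[apply(tb[, -1L, drop = FALSE], 2L, anyNA)]
    stop("channel(s) with missing samples: ", paste(bad, collapse = ", "))
  }
  recording(dat, fs = fs, labels = labels, meta = list(source = path))
}

#' Write a recording as CSV
#'
#' Inverse of the CSV branch of [read_recording()]: header of channel
#' labels, first column `time` in seconds, '.' decimal, UTF-8.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "neurodyn_recording"))
  tb <- data.frame(time = (seq_len(n_samples(rec)) - 1L) / rec$fs,
                   t(rec$data), check.names = FALSE)
  names(tb) <- c("time", rec$labels)
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

# -- EDF ----------------------------------------------------------------------

edf_str <- function(con, nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
edf_num <- function(con, nchars) as.numeric(edf_str(con, nchars))

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  edf_str(con, 8L)                      # version
  edf_str(con, 80L); edf_str(con, 80L)  # patient, recording id
  edf_str(con, 8L); edf_str(con, 8L)    # start date, time
  edf_num(con, 8L)                      # header bytes
  edf_str(con, 44L)                     # reserved
  n_rec <- edf_num(con, 8L)
  rec_dur <- edf_num(con, 8L)
  ns <- as.integer(edf_num(con, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header")
  field <- function(w) vapply(seq_len(ns), function(i) edf_str(con, w), character(1))
  labels <- field(16L)
  field(80L)                            # transducer
  field(8L)                             # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                            # prefiltering
  spr <- as.integer(field(8L))          # samples per record
  field(32L)                            # reserved
  keep <- labels != "EDF Annotations"
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) < spr[i]) stop("truncated EDF data record")
      if (keep[i]) sig[[i]] <- c(sig[[i]], d)
    }
  }
  if (!any(keep)) stop("no signal channels in EDF file")
  fs_all <- spr[keep] / rec_dur
  if (length(unique(fs_all)) != 1L)
    stop("channels with inconsistent sampling rates: ",
         paste(labels[keep][fs_all != fs_all[1L]], collapse = ", "))
  dat <- do.call(rbind, lapply(which(keep), function(i) {
    g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys_min[i] + (sig[[i]] - dig_min[i]) * g
  }))
  recording(dat, fs = fs_all[1L], labels = labels[keep],
            meta = list(source = path, format = "edf"))
}

# -- cohort and tensor persistence -------------------------------------------

#' Write a synthetic cohort to disk
#'
#' One recording CSV per subject (named `<subject_id>.csv`) plus
#' `cohort.csv` (`subject_id`, `age_months`, `sex`) — the same reader path
#' as real data.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings))
    write_recording_csv(cohort$recordings[[id]], file.path(dir, paste0(id, ".csv")))
  utils::write.csv(cohort$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir the cohort directory.
#' @return list with `recordings` (named list) and `cohort` (data.frame).
#' @export
read_cohort <- function(dir) {
  ct <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  recs <- lapply(ct$subject_id, function(id)
    read_recording(file.path(dir, paste0(id, ".csv")), "csv"))
  names(recs) <- ct$subject_id
  list(recordings = recs, cohort = ct)
}

#' Persist a feature tensor as a portable directory
#'
#' `values.csv`/`mask.csv` hold the flattened arrays (column-major) and
#' `axes.json` the dimension sizes and labels, so any array library can
#' rebuild the tensor.
#'
#' @param x a [feature_tensor()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tensor <- function(x, dir) {
  stopifnot(inherits(x, "neurodyn_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(value = as.vector(x$values)),
                   file.path(dir, "values.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mask = as.integer(x$mask)),
                   file.path(dir, "mask.csv"), row.names = FALSE)
  jsonlite::write_json(list(dim = dim(x$values), dimnames = dimnames(x$values)),
                       file.path(dir, "axes.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  ax <- jsonlite::read_json(file.path(dir, "axes.json"), simplifyVector = TRUE)
  vals <- utils::read.csv(file.path(dir, "values.csv"))$value
  mask <- utils::read.csv(file.path(dir, "mask.csv"))$mask
  dims <- as.integer(ax$dim)
  feature_tensor(array(vals, dim = dims, dimnames = ax$dimnames),
                 array(as.logical(mask), dim = dims))
}
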