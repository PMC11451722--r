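# Fixture builders shared across test files. Everything is generated in code
# at test time; nothing binary ships with the package.

# minimal EDF writer (one data record per second, int16 little-endian) used
# to exercise the package's EDF reader on a known signal
write_edf_fixture <- function(path, data, fs, labels,
                              phys_min = -250, phys_max = 250) {
  nch <- nrow(data)
  n <- ncol(data)
  n_rec <- n %/% fs
  stopifnot(n_rec * fs == n)
  pad <- function(s, w) formatC(substr(s, 1, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wchar("0", 8)
  wchar("synthetic fixture", 80)
  wchar("neurodyn test recording", 80)
  wchar("01.01.24", 8); wchar("00.00.00", 8)
  wchar(as.character(256L * (nch + 1L)), 8)
  wchar("", 44)
  wchar(as.character(n_rec), 8)
  wchar("1", 8)
  wchar(as.character(nch), 4)
  for (l in labels) wchar(l, 16)
  for (i in seq_len(nch)) wchar("synthetic", 80)
  for (i in seq_len(nch)) wchar("uV", 8)
  for (i in seq_len(nch)) wchar(as.character(phys_min), 8)
  for (i in seq_len(nch)) wchar(as.character(phys_max), 8)
  for (i in seq_len(nch)) wchar("-32768", 8)
  for (i in seq_len(nch)) wchar("32767", 8)
  for (i in seq_len(nch)) wchar("", 80)
  for (i in seq_len(nch)) wchar(as.character(fs), 8)
  for (i in seq_len(nch)) wchar("", 32)
  gain <- (phys_max - phys_min) / (32767 - (-32768))
  dig <- round((data - phys_min) / gain + (-32768))
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nch))
      writeBin(dig[i, cols], con, size = 2L, endian = "little")
  }
  invisible(path)
}

# exact low-rank feature tensor from given factor matrices
rank_tensor <- function(A, B, C, D, dimnames = NULL) {
  R <- ncol(A)
  dims <- c(nrow(A), nrow(B), nrow(C), nrow(D))
  if (is.null(dimnames))
    dimnames <- list(subject = paste0("S", seq_len(dims[1])),
                     sensor = paste0("c", seq_len(dims[2])),
                     band = paste0("b", seq_len(dims[3])),
                     measure = paste0("m", seq_len(dims[4])))
  vals <- array(0, dim = dims, dimnames = dimnames)
  for (r in seq_len(R))
    vals <- vals + outer(outer(outer(A[, r], B[, r]), C[, r]), D[, r])
  feature_tensor(vals)
}

# small cohort + tensor for pipeline-level tests (kept tiny for speed)
tiny_cohort_tensor <- function(n_subjects = 12, seed = 7,
                               config = feature_config(
                                 measures = c("Power", "RR", "DET", "SampEn", "DFA"),
                                 max_points = 400)) {
  co <- generate_cohort(n_subjects = n_subjects, seed = seed)
  ft <- lapply(co$recordings, extract_features, config = config)
  list(cohort = co, tensor = assemble_tensor(ft, co$cohort))
}
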