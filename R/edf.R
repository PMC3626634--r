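# Minimal EDF (European Data Format) reader and writer.
#
# Supports continuous EDF with 16-bit samples and a common sampling rate
# across signals — sufficient for round-tripping synthetic cohorts and for
# reading plain clinical exports. Physical scaling uses a symmetric range
# per signal; the quantization step is range/32767.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) stop("EDF header field too wide: '", s, "'")
  formatC(s, width = -width, flag = "-")
}

#' Write a multichannel recording as EDF
#'
#' Writes a continuous 16-bit EDF file with 1-second data records. The
#' signal is zero-padded to a whole number of records.
#'
#' @param x Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz (must be a positive integer).
#' @param path Output file path.
#' @param labels Channel labels (default `colnames(x)`).
#' @param physical_dim Unit string stored per signal (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, fs, path, labels = colnames(x),
                      physical_dim = "uV") {
  x <- as.matrix(x)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(ncol(x)))
  stopifnot(fs == round(fs), fs >= 1, length(labels) == ncol(x),
            all(is.finite(x)))
  ns <- ncol(x)
  nrec <- ceiling(nrow(x) / fs)
  if (nrec * fs > nrow(x))
    x <- rbind(x, matrix(0, nrec * fs - nrow(x), ns))

  amp <- apply(abs(x), 2, max)
  amp <- signif(pmax(amp, 1e-6) * 1.001, 4)
  amp_str <- sprintf("%.4g", amp)
  if (any(nchar(amp_str) > 8) || any(nchar(sprintf("-%.4g", amp)) > 8))
    stop("signal amplitude out of the supported EDF physical range")
  dig <- round(sweep(x, 2, amp, "/") * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put("X X X X", 80)                               # patient id
  put("Startdate 01-JAN-2020 X X X", 80)           # recording id
  put("01.01.20", 8); put("00.00.00", 8)
  put(256 * (1 + ns), 8)
  put("", 44)
  put(nrec, 8)
  put("1", 8)                                      # record duration, s
  put(ns, 4)
  for (s in labels) put(s, 16)
  for (s in rep("", ns)) put(s, 80)                # transducer
  for (s in rep(physical_dim, ns)) put(s, 8)
  for (s in sprintf("-%.4g", amp)) put(s, 8)       # physical min
  for (s in amp_str) put(s, 8)                     # physical max
  for (s in rep("-32767", ns)) put(s, 8)           # digital min
  for (s in rep("32767", ns)) put(s, 8)            # digital max
  for (s in rep("", ns)) put(s, 80)                # prefiltering
  for (s in rep(fs, ns)) put(s, 8)                 # samples per record
  for (s in rep("", ns)) put(s, 32)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous EDF file whose signals share one sampling rate.
#'
#' @param path EDF file path.
#' @return A list of class `eeg_record`: `data` (samples x channels matrix
#'   with channel-label column names), `sampling_rate` (Hz), `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  get(8)                                  # version
  get(80); get(80); get(8); get(8)
  header_bytes <- as.integer(get(8))
  reserved <- get(44)
  if (grepl("EDF\\+D", reserved))
    stop("discontinuous EDF+D files are not supported")
  nrec <- as.integer(get(8))
  dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  field <- function(w) vapply(seq_len(ns), function(i) get(w), character(1))
  labels <- field(16)
  field(80)
  field(8)                                # physical dimension
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin_ <- as.numeric(field(8)); dmax_ <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))
  field(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  seek(con, header_bytes)
  raw_n <- nrec * sum(spr)
  v <- readBin(con, integer(), n = raw_n, size = 2, endian = "little",
               signed = TRUE)
  if (length(v) < raw_n) stop("truncated EDF data section")
  # records x (signal-major blocks) -> samples x channels
  arr <- array(v, dim = c(spr[1], ns, nrec))
  data <- matrix(aperm(arr, c(1, 3, 2)), nrow = spr[1] * nrec, ncol = ns)
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- sweep(sweep(data, 2, dmin_), 2, scale, "*")
  data <- sweep(data, 2, pmin_, "+")
  colnames(data) <- labels
  fs <- spr[1] / dur
  structure(list(data = data, sampling_rate = fs, labels = labels),
            class = "eeg_record")
}

#' Write a synthetic cohort to disk as EDF plus sidecar tables
#'
#' One EDF per subject (segments concatenated), a per-subject segment
#' boundary table (`<id>_segments.csv`: `start_s`, `end_s`), and a cohort
#' metadata CSV.
#'
#' @param cohort An `eeg_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Data frame listing the files written, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- lapply(cohort$recordings, function(rec) {
    fs <- rec$sampling_rate
    lens <- vapply(rec$segments, nrow, integer(1))
    ends <- cumsum(lens) / fs
    bounds <- data.frame(start_s = c(0, utils::head(ends, -1)), end_s = ends)
    edf <- file.path(dir, paste0(rec$subject_id, ".edf"))
    seg <- file.path(dir, paste0(rec$subject_id, "_segments.csv"))
    write_edf(do.call(rbind, rec$segments), fs, edf)
    utils::write.csv(bounds, seg, row.names = FALSE)
    data.frame(subject_id = rec$subject_id, edf = edf, segments = seg,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(do.call(rbind, files))
}
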