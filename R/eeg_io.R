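# Recording ingestion and preprocessing: montage mapping, resampling,
# zero-phase FIR filtering (band-pass + notch), average referencing, and
# assembly of the artifact-free segment list.
#
# Fixed order: load -> resample -> notch -> band-pass -> average reference ->
# segment. The whole chain is deterministic.

#' Segmented recording container
#'
#' A per-subject list of artifact-free continuous EEG segments sharing one
#' sampling rate and channel set.
#'
#' @param segments List of numeric matrices (samples x channels), all with
#'   the same channel count.
#' @param sampling_rate Hz.
#' @param subject_id Optional identifier.
#' @return An object of class `segmented_recording`.
#' @export
segmented_recording <- function(segments, sampling_rate, subject_id = NULL) {
  stopifnot(is.list(segments), length(segments) >= 1, sampling_rate > 0)
  nch <- unique(vapply(segments, ncol, integer(1)))
  if (length(nch) != 1)
    stop("all segments must share the same channel count")
  if (!all(vapply(segments, function(s) all(is.finite(s)), logical(1))))
    stop("segments must contain only finite values")
  structure(list(subject_id = subject_id, sampling_rate = sampling_rate,
                 segments = segments),
            class = "segmented_recording")
}

#' @export
print.segmented_recording <- function(x, ...) {
  lens <- vapply(x$segments, nrow, integer(1))
  cat(sprintf("segmented recording%s: %d segment(s), %.1f s total @ %g Hz, %d channels\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              length(lens), sum(lens) / x$sampling_rate, x$sampling_rate,
              ncol(x$segments[[1]])))
  invisible(x)
}

#' Preprocessing configuration
#'
#' @param bandpass Length-2 Hz band-pass edges (default 1-70 Hz FIR).
#' @param notch Power-line notch frequency in Hz (default 60; use 50 where
#'   applicable, `NULL` to disable).
#' @param min_total_duration Minimum total retained artifact-free duration in
#'   seconds (default 120 s); subjects below it are rejected.
#' @param resample_to Optional target sampling rate in Hz to harmonize mixed
#'   source rates (`NULL` = keep native rate).
#' @param amplitude_limit Optional per-sample absolute amplitude veto
#'   (same units as the data); segments exceeding it are dropped. Default
#'   off.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass = c(1, 70), notch = 60,
                              min_total_duration = 120, resample_to = NULL,
                              amplitude_limit = NULL) {
  stopifnot(length(bandpass) == 2, bandpass[1] > 0,
            bandpass[2] > bandpass[1], min_total_duration > 0)
  structure(list(bandpass = bandpass, notch = notch,
                 min_total_duration = min_total_duration,
                 resample_to = resample_to,
                 amplitude_limit = amplitude_limit),
            class = "preprocess_config")
}

#' Load a recording and map channels onto the montage
#'
#' Reads an EDF file, resolves channel labels (including the T7/T8/P7/P8
#' aliases and an optional explicit channel map for high-density inputs),
#' reorders channels to montage order, and drops extra channels.
#'
#' @param path EDF file path.
#' @param montage An `electrode_montage`.
#' @param channel_map Optional named character vector mapping file channel
#'   labels to montage labels (names = file labels).
#' @return An `eeg_record` (list: `data` samples x 19 matrix in montage
#'   order, `sampling_rate`, `labels`).
#' @export
load_recording <- function(path, montage, channel_map = NULL) {
  rec <- read_edf(path)
  labels <- trimws(rec$labels)
  if (!is.null(channel_map)) {
    hit <- match(labels, names(channel_map))
    labels[!is.na(hit)] <- channel_map[hit[!is.na(hit)]]
  }
  labels <- canonical_labels(labels)
  want <- montage$electrodes$name
  idx <- match(want, labels)
  if (anyNA(idx))
    stop("montage channels missing from recording: ",
         paste(want[is.na(idx)], collapse = ", "))
  data <- rec$data[, idx, drop = FALSE]
  colnames(data) <- want
  structure(list(data = data, sampling_rate = rec$sampling_rate,
                 labels = want),
            class = "eeg_record")
}

#' Average reference
#'
#' Subtracts the instantaneous mean across channels from every sample, so
#' the channel mean of the output is 0 at every time point. Idempotent.
#'
#' @param x A samples x channels matrix, an `eeg_record`, or a
#'   [segmented_recording()] (applied per segment).
#' @return Object of the same type, re-referenced.
#' @export
average_reference <- function(x) {
  if (inherits(x, "segmented_recording")) {
    x$segments <- lapply(x$segments, average_reference)
    return(x)
  }
  if (inherits(x, "eeg_record")) {
    x$data <- average_reference(x$data)
    return(x)
  }
  x - rowMeans(x)
}

# Even-order windowed-sinc FIR band-pass; transition width 25% of the lower
# edge gives a filter fully determined by the configuration.
fir_bandpass <- function(low, high, fs, transition = 0.25 * low) {
  n <- 2 * ceiling(3.3 * fs / transition / 2)
  signal::fir1(n, c(low, high) / (fs / 2), type = "pass")
}

fir_notch <- function(f0, fs, half_width = 2) {
  n <- 2 * ceiling(3.3 * fs / half_width / 2)
  signal::fir1(n, c(f0 - half_width, f0 + half_width) / (fs / 2),
               type = "stop")
}

# Zero-phase application of a linear-phase (symmetric, odd-length) FIR:
# single FFT-based convolution pass with reflection padding and exact
# group-delay compensation. The effective amplitude response is |B(f)|.
apply_fir_zerophase <- function(x, b) {
  one <- function(v) {
    n <- length(v)
    P <- length(b)
    if (n < 2) return(v)
    pre <- v[pmin(P, n):1]             # reflected edges
    post <- v[n:pmax(1, n - P + 1)]
    xp <- c(pre, v, post)
    full <- stats::convolve(xp, rev(b), type = "open")
    m <- (P - 1) / 2
    full[(length(pre) + m + 1):(length(pre) + m + n)]
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

# Exact Fourier (sinc) resampling: the spectrum is truncated (ideal
# anti-alias low-pass) or zero-padded and inverse-transformed, with no group
# delay. Appropriate for band-limited signals; mild ringing is possible at
# record edges.
resample_fft <- function(v, n_out) {
  n <- length(v)
  if (n_out == n) return(v)
  X <- stats::fft(v)
  Xo <- complex(length.out = n_out)
  kmax <- min(n, n_out) %/% 2
  Xo[1] <- X[1]
  if (kmax >= 1) {
    ks <- seq_len(kmax - 1)
    Xo[1 + ks] <- X[1 + ks]
    Xo[n_out + 1 - ks] <- X[n + 1 - ks]
    # split the shared Nyquist bin symmetrically
    Xo[1 + kmax] <- X[1 + kmax] / 2
    if (kmax > 0) Xo[n_out + 1 - kmax] <- Conj(X[1 + kmax]) / 2
  }
  Re(stats::fft(Xo, inverse = TRUE)) / n
}

resample_matrix <- function(x, fs, target) {
  if (fs == target) return(x)
  n_out <- round(nrow(x) * target / fs)
  apply(x, 2, resample_fft, n_out = n_out)
}

#' Filter a recording (zero-phase FIR band-pass + notch)
#'
#' Optionally resamples to `config$resample_to`, applies the power-line
#' notch and then the band-pass, both as zero-phase linear-phase FIR filters
#' (windowed sinc, Hamming window, transition width 25% of the lower
#' band-pass edge). Zero-phase application leaves the phase structure — and
#' hence coherence — undistorted. In-band amplitude is preserved within 5%
#' and the notch frequency is attenuated by more than 20 dB.
#'
#' @param record An `eeg_record` (or plain matrix plus `fs`).
#' @param config A [preprocess_config()].
#' @param fs Sampling rate; required when `record` is a bare matrix.
#' @return Filtered object of the same type (with the new sampling rate if
#'   resampled).
#' @export
filter_record <- function(record, config = preprocess_config(), fs = NULL) {
  bare <- !inherits(record, "eeg_record")
  x <- if (bare) as.matrix(record) else record$data
  fs <- if (bare) fs else record$sampling_rate
  if (is.null(fs)) stop("fs is required for matrix input")
  if (!is.null(config$resample_to) && config$resample_to != fs) {
    x <- resample_matrix(x, fs, config$resample_to)
    fs <- config$resample_to
  }
  nyq <- fs / 2
  if (config$bandpass[2] >= nyq)
    stop("band-pass upper edge (", config$bandpass[2],
         " Hz) must be below the Nyquist frequency (", nyq, " Hz)")
  if (!is.null(config$notch)) {
    if (config$notch + 2 >= nyq)
      stop("notch frequency too close to Nyquist")
    x <- apply_fir_zerophase(x, fir_notch(config$notch, fs))
  }
  x <- apply_fir_zerophase(x, fir_bandpass(config$bandpass[1],
                                           config$bandpass[2], fs))
  if (bare) return(x)
  record$data <- x
  record$sampling_rate <- fs
  record
}

#' Assemble the per-subject segment list
#'
#' Cuts a continuous (preprocessed) record into the artifact-free segments
#' given by a boundary table, drops segments shorter than one Welch window
#' (and, when an amplitude limit is configured, segments exceeding it), and
#' rejects the subject if the retained total duration falls below
#' `config$min_total_duration` (condition class
#' `cohgraph_insufficient_data`).
#'
#' @param record An `eeg_record`.
#' @param boundaries Data frame with `start_s` and `end_s` columns
#'   (non-overlapping, within the record).
#' @param config A [preprocess_config()].
#' @param welch A [welch_config()] (defines the minimum usable segment
#'   length).
#' @return A [segmented_recording()]; dropped segments are reported in
#'   `attr(, "dropped")`.
#' @export
assemble_segments <- function(record, boundaries,
                              config = preprocess_config(),
                              welch = welch_config()) {
  stopifnot(inherits(record, "eeg_record"),
            all(c("start_s", "end_s") %in% names(boundaries)))
  fs <- record$sampling_rate
  n <- nrow(record$data)
  b <- boundaries[order(boundaries$start_s), , drop = FALSE]
  if (any(b$end_s <= b$start_s)) stop("segment boundaries must have end > start")
  if (any(b$start_s < 0) || any(b$end_s * fs > n + 0.5))
    stop("segment boundaries outside the record")
  if (nrow(b) > 1 && any(b$start_s[-1] < b$end_s[-nrow(b)]))
    stop("segment boundaries overlap")

  nwin <- round(welch$window_sec * fs)
  segs <- list(); dropped <- character(0)
  for (i in seq_len(nrow(b))) {
    from <- floor(b$start_s[i] * fs) + 1
    to <- min(n, round(b$end_s[i] * fs))
    seg <- record$data[from:to, , drop = FALSE]
    if (nrow(seg) < nwin) {
      dropped <- c(dropped, sprintf("segment %d: shorter than one Welch window", i))
    } else if (!is.null(config$amplitude_limit) &&
               max(abs(seg)) > config$amplitude_limit) {
      dropped <- c(dropped, sprintf("segment %d: amplitude veto", i))
    } else {
      segs <- c(segs, list(seg))
    }
  }
  total <- sum(vapply(segs, nrow, integer(1))) / fs
  if (length(segs) == 0 || total < config$min_total_duration) {
    cond <- structure(
      class = c("cohgraph_insufficient_data", "error", "condition"),
      list(message = sprintf(
        "subject rejected: %.1f s retained, below the %g s minimum",
        total, config$min_total_duration), call = sys.call(-1)))
    stop(cond)
  }
  out <- segmented_recording(segs, fs)
  attr(out, "dropped") <- dropped
  out
}

#' Full preprocessing of one subject
#'
#' Convenience wrapper running the fixed chain: load (or accept an
#' `eeg_record`), resample, notch, band-pass, average reference, and segment
#' assembly.
#'
#' @param input EDF path or `eeg_record`.
#' @param montage An `electrode_montage` (used when `input` is a path).
#' @param boundaries Segment boundary table (`start_s`, `end_s`); `NULL`
#'   treats the whole record as one segment.
#' @param config A [preprocess_config()].
#' @param welch A [welch_config()].
#' @param channel_map Optional channel map passed to [load_recording()].
#' @return A [segmented_recording()].
#' @export
preprocess_subject <- function(input, montage = build_standard_montage(),
                               boundaries = NULL,
                               config = preprocess_config(),
                               welch = welch_config(), channel_map = NULL) {
  rec <- if (inherits(input, "eeg_record")) input
         else load_recording(input, montage, channel_map)
  rec <- filter_record(rec, config)
  rec <- average_reference(rec)
  if (is.null(boundaries))
    boundaries <- data.frame(start_s = 0,
                             end_s = nrow(rec$data) / rec$sampling_rate)
  assemble_segments(rec, boundaries, config, welch)
}
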