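# Magnitude-squared coherence (MSC) per EEG segment and the
# segment-length-weighted band coherence matrix.
#
# Coherence is estimated with Welch's method: Hann-tapered, overlapping
# windows within one continuous artifact-free segment; cross- and
# auto-spectra are averaged over windows and MSC = |Sxy|^2 / (Sxx Syy).
# Segments are never concatenated (transitions between discontinuous
# segments would inject artifactual broadband power); instead per-segment
# in-band coherences are averaged with weights equal to segment length.

#' Welch estimator configuration
#'
#' @param window_sec Window length in seconds (default 2 s, i.e. 0.5 Hz
#'   frequency resolution: at least 8 in-band bins for theta, 4 per alpha
#'   sub-band).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @return A list of class `welch_config`.
#' @export
welch_config <- function(window_sec = 2, overlap = 0.5) {
  stopifnot(window_sec > 0, overlap >= 0, overlap < 1)
  structure(list(window_sec = window_sec, overlap = overlap),
            class = "welch_config")
}

#' Frequency band definition
#'
#' @param name Band name.
#' @param low,high Band edges in Hz; a frequency bin f belongs to the band
#'   when `low <= f < high` (half-open, so adjacent bands do not double-count
#'   their shared edge).
#' @return A list of class `frequency_band`.
#' @export
frequency_band <- function(name, low, high) {
  stopifnot(is.character(name), low < high, low >= 0)
  structure(list(name = name, low = low, high = high),
            class = "frequency_band")
}

#' Default analysis bands
#'
#' Theta (4-8 Hz) and the lower (8-10 Hz) and upper (10-12 Hz) alpha
#' sub-bands: the bands with favourable signal-to-noise ratio in routine
#' clinical EEG and the least contamination by muscle (beta/gamma) and
#' motion (delta) artifact.
#'
#' @return Named list of [frequency_band()] objects.
#' @export
frequency_bands <- function() {
  list(
    theta       = frequency_band("theta", 4, 8),
    lower_alpha = frequency_band("lower_alpha", 8, 10),
    upper_alpha = frequency_band("upper_alpha", 10, 12)
  )
}

# Welch-averaged cross-spectral matrices for all channel pairs.
# x: samples x channels matrix. Returns list(freq, S [p x p x nfreq], n_windows).
welch_cross_spectra <- function(x, fs, welch = welch_config()) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  nwin <- round(welch$window_sec * fs)
  if (n < nwin)
    stop("segment shorter than one Welch window (", nwin, " samples)")
  step <- max(1L, round(nwin * (1 - welch$overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  k <- seq_len(nwin) - 1L
  taper <- 0.5 - 0.5 * cos(2 * pi * k / (nwin - 1))
  nf <- nwin %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / nwin

  Fa <- array(0 + 0i, c(nf, p, length(starts)))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nwin - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))          # per-window demeaning
    X <- stats::mvfft(seg * taper)
    Fa[, , j] <- X[seq_len(nf), , drop = FALSE]
  }
  S <- array(0 + 0i, c(p, p, nf))
  for (f in seq_len(nf)) {
    M <- matrix(Fa[f, , ], nrow = p)
    S[, , f] <- M %*% Conj(t(M))
  }
  list(freq = freq, S = S / length(starts), n_windows = length(starts))
}

#' Magnitude-squared coherence spectrum of one segment
#'
#' Computes Welch-averaged MSC for all channel pairs of one continuous
#' segment, on the Welch frequency grid. MSC lies in `[0, 1]`; the diagonal
#' (a channel with itself) is exactly 1 at every frequency.
#'
#' @param segment Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz.
#' @param welch A [welch_config()].
#' @return An object of class `coherence_spectrum`: list with `freq` (Hz),
#'   `msc` (channels x channels x frequency array) and `n_windows`.
#' @export
segment_coherence <- function(segment, fs, welch = welch_config()) {
  cs <- welch_cross_spectra(segment, fs, welch)
  p <- dim(cs$S)[1]; nf <- length(cs$freq)
  msc <- array(NA_real_, c(p, p, nf))
  for (f in seq_len(nf)) {
    Sf <- cs$S[, , f]
    pw <- Re(diag(Sf))
    den <- outer(pw, pw)
    m <- Mod(Sf)^2 / den
    m[den == 0] <- 0
    diag(m) <- 1
    msc[, , f] <- pmin(pmax(m, 0), 1)
  }
  nm <- colnames(segment)
  dimnames(msc) <- list(nm, nm, NULL)
  structure(list(freq = cs$freq, msc = msc, n_windows = cs$n_windows),
            class = "coherence_spectrum")
}

band_bin_index <- function(freq, band) {
  bins <- which(freq >= band$low & freq < band$high)
  if (length(bins) == 0)
    stop("no frequency bins inside band ", band$name,
         " at this window length / sampling rate")
  bins
}

#' Length-weighted average
#'
#' Averages per-segment quantities (scalars or matrices) with weights equal
#' to segment length, the combination rule of the segment-weighted
#' connectivity measure: longer artifact-free segments count proportionally
#' more and short fragments get negligible weight.
#'
#' @param values Numeric vector, or list of equal-dimension numeric
#'   matrices/vectors (one element per segment).
#' @param lengths Positive numeric weights (segment lengths; any common unit).
#' @return The weighted average (same shape as one element of `values`).
#' @examples
#' segment_weighted_average(c(0.2, 0.6), c(100, 300))  # 0.5
#' @export
segment_weighted_average <- function(values, lengths) {
  lengths <- as.numeric(lengths)
  stopifnot(all(is.finite(lengths)), all(lengths > 0))
  if (is.list(values)) {
    stopifnot(length(values) == length(lengths))
    acc <- values[[1]] * lengths[1]
    for (i in seq_along(values)[-1]) acc <- acc + values[[i]] * lengths[i]
    acc / sum(lengths)
  } else {
    stopifnot(length(values) == length(lengths))
    sum(values * lengths) / sum(lengths)
  }
}

#' Band coherence matrices for a segmented recording
#'
#' For each requested band, computes the 19 x 19 (channels x channels)
#' segment-weighted band coherence matrix: per segment, MSC is averaged over
#' the in-band frequency bins; per pair, segment values are averaged with
#' weights equal to segment length. Segments shorter than one Welch window
#' are skipped. The per-segment spectra are computed once and shared across
#' bands.
#'
#' @param recording A [segmented_recording()].
#' @param bands List of [frequency_band()] (default [frequency_bands()]).
#' @param welch A [welch_config()].
#' @return Named list of `band_coherence` objects (fields `band`, `values`
#'   matrix with unit diagonal, `total_weight` = summed segment duration in
#'   seconds, `n_segments`).
#' @export
band_coherence_matrices <- function(recording, bands = frequency_bands(),
                                    welch = welch_config()) {
  stopifnot(inherits(recording, "segmented_recording"))
  fs <- recording$sampling_rate
  nwin <- round(welch$window_sec * fs)
  usable <- Filter(function(s) nrow(s) >= nwin, recording$segments)
  if (length(usable) == 0)
    stop("no usable segments: all shorter than one Welch window")
  lens <- vapply(usable, nrow, integer(1))

  per_band <- vector("list", length(bands))
  bins <- NULL
  for (i in seq_along(usable)) {
    sp <- segment_coherence(usable[[i]], fs, welch)
    if (is.null(bins)) bins <- lapply(bands, function(b) band_bin_index(sp$freq, b))
    for (bi in seq_along(bands)) {
      bm <- apply(sp$msc[, , bins[[bi]], drop = FALSE], c(1, 2), mean)
      per_band[[bi]] <- c(per_band[[bi]], list(bm))
    }
  }
  out <- lapply(seq_along(bands), function(bi) {
    v <- segment_weighted_average(per_band[[bi]], lens)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    structure(list(band = bands[[bi]], values = v,
                   total_weight = sum(lens) / fs,
                   n_segments = length(usable)),
              class = "band_coherence")
  })
  names(out) <- vapply(bands, function(b) b$name, character(1))
  out
}

#' Segment-weighted band coherence matrix (single band)
#'
#' @inheritParams band_coherence_matrices
#' @param band A single [frequency_band()].
#' @return A `band_coherence` object.
#' @export
weighted_band_coherence <- function(recording, band, welch = welch_config()) {
  band_coherence_matrices(recording, list(band), welch)[[1]]
}

#' @export
print.band_coherence <- function(x, ...) {
  cat(sprintf("band coherence [%s %g-%g Hz]: %d channels, %d segment(s), %.1f s total\n",
              x$band$name, x$band$low, x$band$high, nrow(x$values),
              x$n_segments, x$total_weight))
  invisible(x)
}

as_coherence_matrix <- function(m) {
  if (inherits(m, "band_coherence")) m <- m$values
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(is.finite(m)),
            all(m >= 0), all(m <= 1))
  m
}

#' Mean coherence over all electrode pairs
#'
#' Arithmetic mean of the coherence matrix over all unordered off-diagonal
#' pairs (171 pairs for the 19-channel montage).
#'
#' @param m A `band_coherence` object or a symmetric coherence matrix.
#' @return Scalar in `[0, 1]`.
#' @export
mean_coherence <- function(m) {
  m <- as_coherence_matrix(m)
  mean(m[upper.tri(m)])
}

pair_mean <- function(m, montage, rows) {
  i <- montage_index(montage, rows$a)
  j <- montage_index(montage, rows$b)
  mean(m[cbind(i, j)])
}

#' Inter- over intra-hemispheric coherence ratio
#'
#' Mean coherence over the 8 homologous (left/right mirror-image)
#' inter-hemispheric pairs divided by the mean over the 56 intra-hemispheric
#' non-midline pairs. Sensitive to callosal (direct inter-hemispheric)
#' connectivity.
#'
#' @param m A `band_coherence` or coherence matrix with montage channel order.
#' @param montage An `electrode_montage`.
#' @return Scalar ratio; `NA` (undefined, not clipped) if the denominator is 0.
#' @export
inter_intra_ratio <- function(m, montage) {
  m <- as_coherence_matrix(m)
  p <- montage$pairs
  num <- pair_mean(m, montage, p[p$homologous_interhemispheric, ])
  den <- pair_mean(m, montage, p[p$intra_nonmidline, ])
  if (den == 0) return(NA_real_)
  num / den
}

#' Long- over short-range coherence ratio
#'
#' Mean coherence over long-range pairs (grid distance >= 3) divided by the
#' mean over short-range pairs (2 <= distance < 3). Neighboring pairs
#' (distance < 2) are excluded from both because of excessive volume
#' conduction.
#'
#' @inheritParams inter_intra_ratio
#' @return Scalar ratio; `NA` if the denominator is 0.
#' @export
long_short_ratio <- function(m, montage) {
  m <- as_coherence_matrix(m)
  p <- montage$pairs
  num <- pair_mean(m, montage, p[p$class == "long", ])
  den <- pair_mean(m, montage, p[p$class == "short", ])
  if (den == 0) return(NA_real_)
  num / den
}

#' All three connectivity summaries
#'
#' @inheritParams inter_intra_ratio
#' @return One-row data frame: `mean_coherence`, `inter_intra_ratio`,
#'   `long_short_ratio`.
#' @export
connectivity_summary <- function(m, montage) {
  data.frame(
    mean_coherence = mean_coherence(m),
    inter_intra_ratio = inter_intra_ratio(m, montage),
    long_short_ratio = long_short_ratio(m, montage)
  )
}
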