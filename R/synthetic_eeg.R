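# Synthetic cohorts of segmented multichannel EEG-like signals.
#
# Each channel mixes band-limited latent Gaussian sources:
#   * one network-wide source with a fixed signed (dipole-like) topography,
#     centered to zero mean so it passes through the average reference
#     unchanged — it carries long-range coherence;
#   * five regional sources (four scalp quadrants + a central region) with
#     Gaussian membership weights and fixed per-channel phase offsets chosen
#     so each region's weighted phasor sum is zero (average-reference
#     transparent); they carry short-range coherence that decays with grid
#     distance through membership overlap;
#   * independent per-channel sensor noise, band-limited to the same band so
#     the in-band signal-to-noise ratio is exactly parameterized.
# Mixing is fixed within a segment (stationarity); sources are redrawn per
# segment. Because every source is flat inside the band, the expected
# in-band magnitude-squared coherence of any pair is a closed-form function
# of the mixing weights (see [expected_coherence()]), which is how the
# default gains were calibrated.
#
# Hub electrodes (midline Fz/Cz/Pz by default) get an amplified
# network-wide projection and proportionally reduced sensor noise, making
# them the strongest nodes of the functional graph. Group flags act
# multiplicatively on gains: TSC scales all shared gains down (global
# underconnectivity); ASD scales the network-wide gain down and the
# regional gains up (short-range overconnectivity with long-range
# underconnectivity) and flattens the hub excess (lower hub concentration,
# higher resilience to targeted attack).

#' Synthetic cohort specification
#'
#' Defines the generative conditions of a synthetic EEG cohort with the
#' four-cell group design (control, TSC-only, ASD-only, TSC+ASD), an age
#' covariate, and controllable coherence structure. Defaults are the study
#' conditions used throughout: cell sizes matching the clinical cohort
#' (46/29/16/14), a wide pediatric age range, and gain defaults calibrated
#' (via the closed-form [expected_coherence()]) so that the injected group
#' effects are recoverable by the two-way ANCOVA at these cell sizes.
#'
#' @param n_per_subgroup Integer vector of 4 cell sizes, order
#'   (control, TSC-only, ASD-only, TSC+ASD).
#' @param age_range Years; subject ages are drawn uniformly from this range.
#' @param sampling_rate Hz.
#' @param segment_length_range Seconds; per-segment lengths are uniform in
#'   this range.
#' @param n_segments_range Integer range of segments per subject.
#' @param global_coupling Network-wide shared-source gain in `[0, 1]`.
#' @param local_coupling Regional-source gain.
#' @param region_width Gaussian width (grid units) of the regional
#'   membership kernels.
#' @param beta_tsc_global Multiplicative factor (< 1) on all shared gains
#'   for TSC subjects.
#' @param beta_asd_longshort Factor (< 1) on the network-wide (long-range)
#'   gain for ASD subjects; regional (short-range) gains are scaled by
#'   `2 - beta_asd_longshort` (> 1).
#' @param beta_age Per-year fractional increment of all shared gains.
#' @param hub_gain Hub amplification: hub electrodes project the
#'   network-wide source with `hub_gain` times the base amplitude and have
#'   their sensor noise divided by `sqrt(hub_gain)`.
#' @param hubs Electrode names acting as hubs.
#' @param hub_flattening_asd Factor in `[0, 1]` shrinking the hub excess for
#'   ASD subjects (`hub_gain -> 1 + (hub_gain - 1) * factor`).
#' @param subject_sd Log-normal SD of a per-subject multiplicative jitter on
#'   shared gains (between-subject variability).
#' @param noise_sd Sensor-noise amplitude (unit-variance source scale).
#' @param source_band Hz band of all latent sources (theta/alpha emphasis).
#' @param seed Integer RNG seed; fully determines the cohort.
#' @return A list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_per_subgroup = c(46, 29, 16, 14),
                                  age_range = c(1, 16),
                                  sampling_rate = 250,
                                  segment_length_range = c(40, 60),
                                  n_segments_range = c(3, 5),
                                  global_coupling = 0.6,
                                  local_coupling = 1.2,
                                  region_width = 1,
                                  beta_tsc_global = 0.75,
                                  beta_asd_longshort = 0.7,
                                  beta_age = 0.01,
                                  hub_gain = 2.5,
                                  hubs = c("Fz", "Cz", "Pz"),
                                  hub_flattening_asd = 0.25,
                                  subject_sd = 0.1,
                                  noise_sd = 0.5,
                                  source_band = c(4, 12),
                                  seed = 1) {
  spec <- list(n_per_subgroup = as.integer(n_per_subgroup),
               age_range = age_range, sampling_rate = sampling_rate,
               segment_length_range = segment_length_range,
               n_segments_range = as.integer(n_segments_range),
               global_coupling = global_coupling,
               local_coupling = local_coupling,
               region_width = region_width,
               beta_tsc_global = beta_tsc_global,
               beta_asd_longshort = beta_asd_longshort,
               beta_age = beta_age, hub_gain = hub_gain, hubs = hubs,
               hub_flattening_asd = hub_flattening_asd,
               subject_sd = subject_sd, noise_sd = noise_sd,
               source_band = source_band, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "synthetic_cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (length(n_per_subgroup) != 4 || any(n_per_subgroup < 1))
      stop("n_per_subgroup must give >= 1 subject for each of the 4 cells")
    if (global_coupling < 0 || global_coupling > 1)
      stop("global_coupling must lie in [0, 1]")
    if (local_coupling < 0 || noise_sd < 0 || subject_sd < 0 ||
        region_width <= 0)
      stop("gains, noise scales and region_width must be non-negative")
    if (beta_tsc_global <= 0 || beta_asd_longshort <= 0 ||
        beta_asd_longshort >= 2)
      stop("group gain factors must be positive (beta_asd_longshort < 2)")
    if (hub_gain < 1 || hub_flattening_asd < 0 || hub_flattening_asd > 1)
      stop("hub_gain must be >= 1 and hub_flattening_asd in [0, 1]")
    if (beta_age < 0) stop("beta_age must be non-negative")
    if (source_band[1] <= 0 || source_band[2] >= sampling_rate / 2)
      stop("source_band must lie strictly inside (0, Nyquist)")
    if (segment_length_range[1] < 4)
      stop("segments must be at least a few seconds long")
  })
  invisible(spec)
}

# Deterministic 31-bit seed stream: per-subject substreams independent of
# cohort order.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  ((s * 48271 + as.double(index) * 131071 + 11) %% m) + 1
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# In-band complex Fourier coefficients for spectral synthesis.
bl_bins <- function(n, fs, band) {
  f <- (seq_len(n) - 1) * fs / n
  half <- seq_len(n %/% 2 + 1)
  keep <- half[f[half] >= band[1] & f[half] <= band[2] & half > 1]
  if (length(keep) == 0) stop("band contains no FFT bin at this length")
  keep
}

bl_synthesize <- function(n, keep, coef) {
  spec <- complex(length.out = n)
  spec[keep] <- coef
  mirror <- n - keep + 2
  ok <- mirror <= n & mirror != keep
  spec[mirror[ok]] <- Conj(coef[ok])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Band-limited unit-variance Gaussian noise
#'
#' Generates a zero-mean signal with power confined exactly to the given
#' frequency band (spectral synthesis: independent complex-Gaussian Fourier
#' coefficients on the in-band bins, zero elsewhere), normalized to unit
#' sample variance. The in-band power spectral density is flat in
#' expectation, which makes analytic coherence oracles exact.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 Hz band (must contain at least one FFT bin).
#' @return Numeric vector of length `n` with `sd(x) == 1`.
#' @export
bandlimited_noise <- function(n, fs, band = c(4, 12)) {
  stopifnot(n > 1, band[1] >= 0, band[2] > band[1], band[2] <= fs / 2)
  keep <- bl_bins(n, fs, band)
  coef <- stats::rnorm(length(keep)) + 1i * stats::rnorm(length(keep))
  x <- bl_synthesize(n, keep, coef)
  as.numeric(x / stats::sd(x))
}

# A band-limited source together with its quadrature (90 degree phase
# shifted) companion, from one coefficient draw: channel projections with a
# complex weight w are realized as Re(w) * z + Im(w) * h.
bl_source_pair <- function(n, fs, band) {
  keep <- bl_bins(n, fs, band)
  coef <- stats::rnorm(length(keep)) + 1i * stats::rnorm(length(keep))
  z <- bl_synthesize(n, keep, coef)
  h <- bl_synthesize(n, keep, -1i * coef)
  s <- stats::sd(z)
  list(z = as.numeric(z / s), h = as.numeric(h / s))
}

# Fixed signed topography of the network-wide source: anterior rows project
# with positive, posterior rows with negative polarity (left-positive on the
# central row). Sign is irrelevant to MSC; the pattern only ensures the
# source is not a common mode.
global_topography <- function(montage) {
  el <- montage$electrodes
  s <- ifelse(el$grid_y > 0, 1, ifelse(el$grid_y < 0, -1,
                                       ifelse(el$grid_x <= 0, 1, -1)))
  stats::setNames(s, el$name)
}

# Gaussian membership weights of the five regional sources (four quadrant
# centers + one central), rows = channels.
region_weights <- function(montage, rho) {
  el <- montage$electrodes
  centers <- rbind(c(-1.25, 1), c(1.25, 1), c(-1.25, -1), c(1.25, -1),
                   c(0, 0))
  W <- vapply(seq_len(nrow(centers)), function(r)
    exp(-((el$grid_x - centers[r, 1])^2 + (el$grid_y - centers[r, 2])^2) /
          (2 * rho^2)), numeric(nrow(el)))
  rownames(W) <- el$name
  W
}

# Deterministic per-channel phase offsets making each region's weighted
# phasor sum (the common mode seen by the average reference) vanish:
# channels are visited in decreasing weight order and each is phased
# opposite the running sum.
zero_sum_phases <- function(W) {
  Th <- matrix(0, nrow(W), ncol(W))
  for (r in seq_len(ncol(W))) {
    ord <- order(-W[, r])
    s <- 0 + 0i
    for (c in ord) {
      th <- if (Mod(s) < 1e-12) 0 else Arg(-s)
      Th[c, r] <- th
      s <- s + W[c, r] * exp(1i * th)
    }
  }
  Th
}

# The subject-level mixing model: complex channel x source mixing matrix
# (network-wide column(s) first) and the per-channel noise SDs.
subject_mixing <- function(spec, montage, asd, tsc, age, jitter = 1,
                           acc = FALSE) {
  el <- montage$electrodes
  shared <- (1 + spec$beta_age * age) *
    (if (tsc) spec$beta_tsc_global else 1) * jitter
  ga <- spec$global_coupling * shared *
    (if (asd) spec$beta_asd_longshort else 1)
  la <- spec$local_coupling * shared *
    (if (asd) 2 - spec$beta_asd_longshort else 1)
  hg <- if (asd) 1 + (spec$hub_gain - 1) * spec$hub_flattening_asd
        else spec$hub_gain
  hub_mult <- rep(1, 19)
  hub_mult[montage_index(montage, spec$hubs)] <- hg
  noise <- rep(spec$noise_sd, 19)
  noise[montage_index(montage, spec$hubs)] <- spec$noise_sd / sqrt(hg)

  t0 <- global_topography(montage) * hub_mult
  if (acc) {
    hemi <- el$hemisphere
    mL <- ifelse(hemi == "left", 1, ifelse(hemi == "midline", 1 / sqrt(2), 0))
    mR <- ifelse(hemi == "right", 1, ifelse(hemi == "midline", 1 / sqrt(2), 0))
    tL <- t0 * mL; tL <- tL - mean(tL)
    tR <- t0 * mR; tR <- tR - mean(tR)
    Mg <- ga * cbind(tL, tR)
  } else {
    t1 <- t0 - mean(t0)
    Mg <- ga * cbind(t1)
  }
  W0 <- region_weights(montage, spec$region_width)
  Wc <- la * W0 * exp(1i * zero_sum_phases(W0))
  list(M = cbind(Mg, Wc), noise = noise)
}

#' Expected in-band coherence matrix of the generative model
#'
#' Closed-form expected magnitude-squared coherence for a subject with the
#' given group flags and age: because every latent source is spectrally flat
#' inside the source band, the in-band cross-spectral matrix is
#' `P = M M^H + diag(noise^2)` for the mixing matrix `M`, and
#' `MSC_ij = |P_ij|^2 / (P_ii P_jj)`. Used to calibrate the default gains
#' and as a fast reference in tests (estimates from generated signals
#' converge to these values as recording length grows).
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param asd,tsc,acc Group flags as in [generate_subject()].
#' @param age Age in years.
#' @param average_referenced Return the coherence of the average-referenced
#'   channels (the pipeline's reference; default `TRUE`).
#' @return A 19 x 19 symmetric matrix with unit diagonal.
#' @export
expected_coherence <- function(spec, asd = FALSE, tsc = FALSE, acc = FALSE,
                               age = mean(spec$age_range),
                               average_referenced = TRUE) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  montage <- build_standard_montage()
  mix <- subject_mixing(spec, montage, asd, tsc, age, jitter = 1, acc = acc)
  P <- mix$M %*% Conj(t(mix$M)) + diag(mix$noise^2)
  if (average_referenced) {
    R <- diag(19) - matrix(1 / 19, 19, 19)
    P <- R %*% P %*% R
  }
  msc <- Mod(P)^2 / outer(Re(diag(P)), Re(diag(P)))
  diag(msc) <- 1
  dimnames(msc) <- list(montage$electrodes$name, montage$electrodes$name)
  msc
}

#' Generate one synthetic subject
#'
#' Draws a segmented 19-channel recording whose coherence structure follows
#' the cohort specification modulated by the subject's group flags and age.
#' All latent sources are redrawn per segment (segments are mutually
#' independent realizations of the same stationary process).
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param asd,tsc Logical group flags.
#' @param age Age in years.
#' @param acc If `TRUE`, the network-wide source is split into independent
#'   left- and right-hemisphere sources (callosal disconnection): homologous
#'   inter-hemispheric coherence collapses while intra-hemispheric structure
#'   is preserved. Midline channels receive both hemispheric sources.
#' @param subject_seed Integer seed for this subject (defaults to
#'   `spec$seed`).
#' @param subject_id Identifier stored in the recording.
#' @return A [segmented_recording()].
#' @export
generate_subject <- function(spec, asd = FALSE, tsc = FALSE,
                             age = mean(spec$age_range), acc = FALSE,
                             subject_seed = spec$seed,
                             subject_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  montage <- build_standard_montage()
  fs <- spec$sampling_rate

  with_seed(subject_seed, {
    jitter <- exp(stats::rnorm(1, 0, spec$subject_sd))
    mix <- subject_mixing(spec, montage, asd, tsc, age, jitter, acc)
    M <- mix$M
    n_global <- ncol(M) - 5

    n_seg <- if (spec$n_segments_range[1] == spec$n_segments_range[2])
      spec$n_segments_range[1]
    else sample(spec$n_segments_range[1]:spec$n_segments_range[2], 1)
    seg_secs <- stats::runif(n_seg, spec$segment_length_range[1],
                             spec$segment_length_range[2])

    segments <- lapply(seg_secs, function(secs) {
      nsamp <- round(secs * fs)
      x <- matrix(0, nsamp, 19)
      for (s in seq_len(n_global)) {
        G <- bandlimited_noise(nsamp, fs, spec$source_band)
        x <- x + G %o% Re(M[, s])
      }
      for (r in seq_len(5)) {
        src <- bl_source_pair(nsamp, fs, spec$source_band)
        w <- M[, n_global + r]
        x <- x + src$z %o% Re(w) + src$h %o% Im(w)
      }
      E <- vapply(seq_len(19), function(i)
        bandlimited_noise(nsamp, fs, spec$source_band), numeric(nsamp))
      x <- x + sweep(E, 2, mix$noise, "*")
      colnames(x) <- montage$electrodes$name
      x
    })
    segmented_recording(segments, fs, subject_id = subject_id)
  })
}

#' Generate a synthetic four-cell cohort
#'
#' Generates `sum(n_per_subgroup)` subjects with the requested group-flag
#' combinations, ages drawn uniformly from `spec$age_range`, and a random
#' sex label for the demographics table. Per-subject seeds are derived from
#' the cohort seed by a counter-based substream, so a subject's recording
#' does not depend on cohort order, and the same spec yields bit-identical
#' cohorts.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A list of class `eeg_cohort`: `recordings` (list of
#'   [segmented_recording()]) and `metadata` (data frame: `subject_id`,
#'   `ASD`, `TSC`, `age`, `sex`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n <- spec$n_per_subgroup
  flags <- data.frame(
    TSC = c(rep(0L, n[1]), rep(1L, n[2]), rep(0L, n[3]), rep(1L, n[4])),
    ASD = c(rep(0L, n[1]), rep(0L, n[2]), rep(1L, n[3]), rep(1L, n[4])))
  ntot <- nrow(flags)
  meta <- with_seed(derive_seed(spec$seed, 0), data.frame(
    subject_id = sprintf("S%03d", seq_len(ntot)),
    ASD = flags$ASD, TSC = flags$TSC,
    age = stats::runif(ntot, spec$age_range[1], spec$age_range[2]),
    sex = sample(c("M", "F"), ntot, replace = TRUE),
    stringsAsFactors = FALSE))
  recordings <- lapply(seq_len(ntot), function(i)
    generate_subject(spec, asd = meta$ASD[i] == 1, tsc = meta$TSC[i] == 1,
                     age = meta$age[i],
                     subject_seed = derive_seed(spec$seed, i),
                     subject_id = meta$subject_id[i]))
  structure(list(recordings = recordings, metadata = meta),
            class = "eeg_cohort")
}

#' Generate a callosal-disconnection validation cohort
#'
#' Generates `n_acc` subjects with an absent inter-hemispheric shared source
#' (independent left/right network-wide sources, intra-hemispheric structure
#' untouched) and `n_control` intact control subjects, all without group
#' flags. Used to validate that the inter/intra-hemispheric coherence ratio
#' is sensitive to direct inter-hemispheric (callosal) connectivity.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param n_acc,n_control Group sizes (defaults mirror the clinical
#'   validation sample: 16 vs 46).
#' @return A list of class `eeg_cohort` whose metadata carries an `ACC`
#'   indicator column.
#' @export
generate_acc_cohort <- function(spec, n_acc = 16, n_control = 46) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"), n_acc >= 2,
            n_control >= 2)
  ntot <- n_acc + n_control
  meta <- with_seed(derive_seed(spec$seed, 0), data.frame(
    subject_id = sprintf("S%03d", seq_len(ntot)),
    ACC = c(rep(1L, n_acc), rep(0L, n_control)),
    ASD = 0L, TSC = 0L,
    age = stats::runif(ntot, spec$age_range[1], spec$age_range[2]),
    sex = sample(c("M", "F"), ntot, replace = TRUE),
    stringsAsFactors = FALSE))
  recordings <- lapply(seq_len(ntot), function(i)
    generate_subject(spec, acc = meta$ACC[i] == 1, age = meta$age[i],
                     subject_seed = derive_seed(spec$seed, i),
                     subject_id = meta$subject_id[i]))
  structure(list(recordings = recordings, metadata = meta),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("synthetic EEG cohort:", length(x$recordings), "subjects\n")
  print(utils::head(x$metadata))
  invisible(x)
}
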