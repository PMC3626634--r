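test_that("average reference zeroes the channel mean at every sample", {
  set.seed(71)
  x <- matrix(rnorm(500 * 19), ncol = 19) + rep(1:19, each = 500)
  y <- average_reference(x)
  expect_lt(max(abs(rowMeans(y))), 1e-12)
  # a common constant offset is removed entirely
  const <- matrix(5, 100, 19)
  expect_equal(max(abs(average_reference(const))), 0)
  # distinct per-channel constants leave zero-mean rows
  dc <- matrix(rep(1:19, each = 100), ncol = 19)
  expect_lt(max(abs(rowMeans(average_reference(dc)))), 1e-12)
  # idempotence
  expect_equal(average_reference(y), y, tolerance = 1e-14)
})

test_that("the FIR chain preserves the passband and kills notch and drift", {
  fs <- 250
  t <- (0:(40 * fs - 1)) / fs
  x <- cbind(sin(2 * pi * 10 * t), sin(2 * pi * 60 * t),
             sin(2 * pi * 0.2 * t))
  y <- filter_record(x, preprocess_config(bandpass = c(1, 70), notch = 60),
                     fs = fs)
  mid <- (10 * fs):(30 * fs)            # avoid edge transients
  a10 <- sine_amplitude(y[mid, 1], 10, fs)
  a60 <- sine_amplitude(y[mid, 2], 60, fs)
  adrift <- sine_amplitude(y[mid, 3], 0.2, fs)
  expect_gt(a10, 0.95)
  expect_lt(a10, 1.05)
  expect_lt(a60, 0.1)                   # >= 20 dB attenuation
  expect_lt(adrift, 0.1)
  # zero-phase: the passband sinusoid is not shifted
  expect_gt(cor(y[mid, 1], x[mid, 1]), 0.999)
})

test_that("filter configuration is validated against the sampling rate", {
  x <- matrix(rnorm(1000), ncol = 2)
  expect_error(filter_record(x, preprocess_config(bandpass = c(1, 70)),
                             fs = 100), "Nyquist")
  expect_error(filter_record(x, preprocess_config(bandpass = c(1, 40),
                                                  notch = 49),
                             fs = 100), "notch")
  expect_error(filter_record(x, preprocess_config()), "fs is required")
})

test_that("resampling harmonizes the rate and preserves band content", {
  fs <- 200
  t <- (0:(20 * fs - 1)) / fs
  x <- matrix(sin(2 * pi * 8 * t), ncol = 1)
  y <- filter_record(x, preprocess_config(bandpass = c(1, 45), notch = NULL,
                                          resample_to = 100), fs = fs)
  expect_equal(nrow(y), 20 * 100, tolerance = 2)
  t2 <- (seq_len(nrow(y)) - 1) / 100
  mid <- (5 * 100):(15 * 100)
  expect_gt(abs(cor(y[mid, 1], sin(2 * pi * 8 * t2[mid]))), 0.999)
})

test_that("EDF files round-trip within quantization error", {
  set.seed(72)
  x <- matrix(rnorm(6 * 128 * 19, sd = 20), ncol = 19)
  colnames(x) <- build_standard_montage()$electrodes$name
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, 128, path)
  back <- read_edf(path)
  expect_equal(back$sampling_rate, 128)
  expect_equal(back$labels, colnames(x))
  q <- max(abs(x)) * 1.001 / 32767
  expect_lt(max(abs(back$data[seq_len(nrow(x)), ] - x)), 1.5 * q)
})

test_that("recordings map onto the montage through aliases and channel maps", {
  set.seed(73)
  m <- build_standard_montage()
  labels <- m$electrodes$name
  labels[labels == "T3"] <- "T7"; labels[labels == "T4"] <- "T8"
  labels[labels == "T5"] <- "P7"; labels[labels == "T6"] <- "P8"
  x <- matrix(rnorm(256 * 21, sd = 10), ncol = 21)
  colnames(x) <- c(rev(labels), "ECG", "E77")   # scrambled order + extras
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, 128, path)
  rec <- load_recording(path, m, channel_map = c(E77 = "ignored"))
  expect_equal(rec$labels, m$electrodes$name)
  expect_equal(ncol(rec$data), 19)
  # signals equal the mapped originals (up to EDF quantization)
  expect_lt(max(abs(rec$data[, "T3"] - x[, colnames(x) == "T7"])), 0.01)

  # a missing montage channel is a hard error naming the label
  x2 <- x[, -1]
  path2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(x2, 128, path2)
  expect_error(load_recording(path2, m), "O2")
})

test_that("segment assembly enforces the minimum-duration rule", {
  m <- build_standard_montage()
  fs <- 128
  x <- matrix(rnorm(200 * fs * 19), ncol = 19)
  colnames(x) <- m$electrodes$name
  rec <- structure(list(data = x, sampling_rate = fs,
                        labels = colnames(x)), class = "eeg_record")
  cfg <- preprocess_config(min_total_duration = 120)

  ok <- assemble_segments(rec, data.frame(start_s = c(0, 65, 130),
                                          end_s = c(60, 125, 190)), cfg)
  expect_length(ok$segments, 3)
  expect_equal(sum(vapply(ok$segments, nrow, integer(1))) / fs, 180)

  # 90 s total falls below the two-minute minimum
  err <- tryCatch(
    assemble_segments(rec, data.frame(start_s = c(0, 100),
                                      end_s = c(45, 145)), cfg),
    condition = function(c) c)
  expect_s3_class(err, "cohgraph_insufficient_data")

  # a one-second fragment is dropped, the rest kept
  withdrop <- assemble_segments(
    rec, data.frame(start_s = c(0, 61, 130), end_s = c(60, 62, 195)), cfg)
  expect_length(withdrop$segments, 2)
  expect_match(attr(withdrop, "dropped"), "shorter than one Welch")

  expect_error(assemble_segments(
    rec, data.frame(start_s = c(0, 30), end_s = c(40, 70)), cfg), "overlap")
  expect_error(assemble_segments(
    rec, data.frame(start_s = 0, end_s = 300), cfg), "outside")
})

test_that("amplitude-vetoed segments are excluded when configured", {
  m <- build_standard_montage()
  fs <- 128
  x <- matrix(rnorm(300 * fs * 19), ncol = 19)
  x[20 * fs, 3] <- 500                  # one artifactual spike
  colnames(x) <- m$electrodes$name
  rec <- structure(list(data = x, sampling_rate = fs, labels = colnames(x)),
                   class = "eeg_record")
  cfg <- preprocess_config(min_total_duration = 100, amplitude_limit = 100)
  out <- assemble_segments(rec, data.frame(start_s = c(0, 70, 160),
                                           end_s = c(60, 130, 280)), cfg)
  expect_length(out$segments, 2)
  expect_match(attr(out, "dropped"), "amplitude veto")
})

test_that("full preprocessing of an EDF subject is deterministic", {
  spec <- quick_spec(n_per_subgroup = c(1, 1, 1, 1), seed = 31)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort_edf(cohort, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  cfg <- preprocess_config(bandpass = c(1, 45), notch = 60,
                           min_total_duration = 30)
  bounds <- read.csv(file.path(dir, "S001_segments.csv"))
  run <- function() preprocess_subject(file.path(dir, "S001.edf"),
                                       boundaries = bounds, config = cfg)
  a <- run(); b <- run()
  expect_identical(a, b)
  expect_equal(length(a$segments), nrow(bounds))
  # channel means are zero after average referencing
  expect_lt(max(abs(rowMeans(a$segments[[1]]))), 1e-9)
})
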