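test_that("cohort generation is deterministic and bookkeeping is exact", {
  spec <- quick_spec(n_per_subgroup = c(2, 1, 1, 1), seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$recordings, b$recordings)
  expect_length(a$recordings, 5)
  expect_equal(a$metadata$TSC, c(0, 0, 1, 0, 1))
  expect_equal(a$metadata$ASD, c(0, 0, 0, 1, 1))
  expect_true(all(a$metadata$age >= spec$age_range[1] &
                    a$metadata$age <= spec$age_range[2]))
  # a different seed changes the data
  c <- generate_cohort(quick_spec(n_per_subgroup = c(2, 1, 1, 1), seed = 100))
  expect_false(identical(a$recordings[[1]], c$recordings[[1]]))
})

test_that("subjects do not depend on cohort composition", {
  s1 <- quick_spec(n_per_subgroup = c(2, 1, 1, 1), seed = 7)
  s2 <- quick_spec(n_per_subgroup = c(2, 2, 2, 2), seed = 7)
  a <- generate_cohort(s1)
  b <- generate_cohort(s2)
  expect_identical(a$recordings[[1]]$segments, b$recordings[[1]]$segments)
})

test_that("a single noiseless shared source makes all pairs fully coherent", {
  spec <- quick_spec(local_coupling = 0, noise_sd = 0, subject_sd = 0,
                     n_segments_range = c(1, 1),
                     segment_length_range = c(30, 30))
  rec <- generate_subject(spec, subject_seed = 5)
  bc <- weighted_band_coherence(rec, frequency_band("src", 4, 12))
  expect_true(all(bc$values[upper.tri(bc$values)] > 1 - 1e-8))
})

test_that("independent noise alone approaches zero coherence with more data", {
  spec_short <- quick_spec(global_coupling = 0, local_coupling = 0,
                           subject_sd = 0, n_segments_range = c(1, 1),
                           segment_length_range = c(20, 20))
  spec_long <- quick_spec(global_coupling = 0, local_coupling = 0,
                          subject_sd = 0, n_segments_range = c(4, 4),
                          segment_length_range = c(60, 60))
  band <- frequency_band("src", 4, 12)
  mc_short <- mean_coherence(weighted_band_coherence(
    generate_subject(spec_short, subject_seed = 3), band))
  mc_long <- mean_coherence(weighted_band_coherence(
    generate_subject(spec_long, subject_seed = 3), band))
  expect_lt(mc_long, mc_short)
  expect_lt(mc_long, 0.06)
})

test_that("a shared source at 1:1 power gives the analytic 0.25 coherence", {
  set.seed(61)
  fs <- 128
  n <- 120 * fs                         # ~119 Welch windows
  s <- bandlimited_noise(n, fs, c(4, 12))
  x1 <- s + bandlimited_noise(n, fs, c(4, 12))
  x2 <- s + bandlimited_noise(n, fs, c(4, 12))
  sp <- segment_coherence(cbind(x1, x2), fs)
  bins <- which(sp$freq >= 5 & sp$freq <= 11)
  got <- mean(sp$msc[1, 2, bins])
  expect_lt(abs(got - 0.25), 0.05)
})

test_that("coherence estimates converge to the closed-form expectation", {
  spec <- quick_spec(subject_sd = 0, n_segments_range = c(6, 6),
                     segment_length_range = c(60, 60))
  rec <- average_reference(generate_subject(spec, subject_seed = 8, age = 8))
  bc <- weighted_band_coherence(rec, frequency_band("src", 4.5, 11.5))
  expected <- expected_coherence(spec, age = 8)
  ut <- upper.tri(expected)
  expect_lt(mean(abs(bc$values[ut] - expected[ut])), 0.03)
})

test_that("expected coherence responds monotonically to the model knobs", {
  base <- quick_spec(subject_sd = 0)
  m <- build_standard_montage()
  ut <- upper.tri(matrix(0, 19, 19))
  pick <- function(msc, rows) {
    i <- match(rows$a, m$electrodes$name); j <- match(rows$b, m$electrodes$name)
    mean(msc[cbind(i, j)])
  }
  long_pairs <- m$pairs[m$pairs$class == "long", ]
  hom <- m$pairs[m$pairs$homologous_interhemispheric, ]

  # stronger global coupling -> more long-range coherence
  lo <- expected_coherence(quick_spec(subject_sd = 0, global_coupling = 0.4))
  hi <- expected_coherence(quick_spec(subject_sd = 0, global_coupling = 0.8))
  expect_gt(pick(hi, long_pairs), pick(lo, long_pairs))

  # TSC scales all shared gains down -> lower mean coherence at matched age
  expect_lt(mean(expected_coherence(base, tsc = TRUE)[ut]),
            mean(expected_coherence(base)[ut]))
  # age increases shared gains -> higher mean coherence
  expect_gt(mean(expected_coherence(base, age = 15)[ut]),
            mean(expected_coherence(base, age = 2)[ut]))
  # ASD shifts the long/short balance downward
  expect_lt(long_short_ratio(expected_coherence(base, asd = TRUE), m),
            long_short_ratio(expected_coherence(base), m))
  # callosal disconnection collapses homologous coherence
  expect_lt(pick(expected_coherence(base, acc = TRUE), hom),
            0.3 * pick(expected_coherence(base), hom))
})

test_that("simulated TSC subjects have lower mean coherence than controls", {
  spec <- quick_spec()
  band <- frequency_band("src", 4, 12)
  mc <- function(tsc, i) mean_coherence(weighted_band_coherence(
    average_reference(generate_subject(spec, tsc = tsc, age = 8,
                                       subject_seed = 400 + i)), band))
  ctrl <- vapply(1:8, function(i) mc(FALSE, i), numeric(1))
  tsc <- vapply(1:8, function(i) mc(TRUE, i), numeric(1))
  expect_lt(t.test(tsc, ctrl, alternative = "less")$p.value, 0.05)
})

test_that("ACC cohorts have collapsed homologous coherence, controls intact", {
  spec <- quick_spec(seed = 12)
  cohort <- generate_acc_cohort(spec, n_acc = 3, n_control = 3)
  expect_equal(cohort$metadata$ACC, c(1, 1, 1, 0, 0, 0))
  m <- build_standard_montage()
  band <- frequency_band("src", 4, 12)
  ratios <- vapply(cohort$recordings, function(r)
    inter_intra_ratio(weighted_band_coherence(average_reference(r), band), m),
    numeric(1))
  expect_lt(max(ratios[1:3]), min(ratios[4:6]))
})

test_that("invalid generator configurations are rejected", {
  expect_error(quick_spec(global_coupling = 1.5), "\\[0, 1\\]")
  expect_error(quick_spec(n_per_subgroup = c(2, 2, 0, 2)), ">= 1")
  expect_error(quick_spec(hub_gain = 0.5), "hub_gain")
  expect_error(quick_spec(source_band = c(4, 80)), "Nyquist")
})

test_that("band-limited noise has unit variance and in-band power only", {
  set.seed(62)
  x <- bandlimited_noise(4000, 100, c(10, 20))
  expect_equal(sd(x), 1, tolerance = 1e-12)
  spec <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * 100 / length(x)
  half <- f <= 50
  inband <- half & f >= 10 & f <= 20
  expect_gt(sum(spec[inband]) / sum(spec[half]), 0.999)
})
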