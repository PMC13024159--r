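make_sine_rec <- function(freq, sfreq, n, amp = 1) {
  new_recording(matrix(amp * sin(2 * pi * freq * (0:(n - 1L)) / sfreq), 1L), sfreq)
}

test_that("resample rate/length contracts hold", {
  rec <- make_sine_rec(10, 1000, 5000)
  expect_identical(resample(rec, 1000), rec)              # identity
  out <- resample(rec, 200)
  expect_equal(out$sfreq, 200)
  expect_equal(ncol(out$signals), 1000L)                  # round(5000 * 200/1000)
  expect_warning(resample(make_sine_rec(5, 100, 200), 250), "upsampl")
  expect_error(resample(rec, -10), "target_sfreq")
})

test_that("resampled sinusoid matches its closed form", {
  rec <- make_sine_rec(10, 1000, 5000)
  out <- resample(rec, 200)
  ref <- sin(2 * pi * 10 * (0:999) / 200)
  keep <- 30:970                                          # trim filter edges
  expect_gt(cor(out$signals[1L, keep], ref[keep]), 0.99)
})

test_that("resample round trip preserves a band-limited sinusoid", {
  for (s in 1:3) {
    f <- c(4, 11, 23)[s]
    rec <- make_sine_rec(f, 200, 2000)
    back <- resample(resample(rec, 120), 200, upsample = TRUE)
    keep <- 50:1900
    expect_gt(cor(back$signals[1L, keep], rec$signals[1L, keep]), 0.99)
  }
})

test_that("bandpass rejects DC and passes in-band sinusoids", {
  dc <- new_recording(matrix(5, 1L, 2000L), 200)
  out <- bandpass(dc, 0.3, 75)
  expect_lt(mean(abs(out$signals)), 0.05)                 # < 1% of amplitude 5
  s10 <- make_sine_rec(10, 200, 2000)
  out10 <- bandpass(s10, 0.3, 75)
  gain_db <- 20 * log10(sqrt(mean(out10$signals^2)) / sqrt(mean(s10$signals^2)))
  expect_lt(abs(gain_db), 1)
})

test_that("bandpass stop-band attenuation matches the squared Butterworth response", {
  s90 <- make_sine_rec(90, 200, 2000)
  out90 <- bandpass(s90, 0.3, 75)
  atten_db <- -20 * log10(sqrt(mean(out90$signals^2)) / sqrt(mean(s90$signals^2)))
  expect_gt(atten_db, 12)
  # the zero-phase (two-pass) filter must attenuate the steady-state section
  # at least as much as one analytic prewarped 4th-order Butterworth pass;
  # edge-reflection leakage keeps the measured value below the squared ideal
  mid <- 500:1500
  mid_db <- -20 * log10(sqrt(mean(out90$signals[1L, mid]^2)) /
                          sqrt(mean(s90$signals[1L, mid]^2)))
  ratio <- tan(pi * 90 / 200) / tan(pi * 75 / 200)
  expect_gt(mid_db, 10 * log10(1 + ratio^8))
  expect_error(bandpass(s90, 0.3, 120), "sfreq/2")
})

test_that("bandpass strictly reduces stop-band energy on random signals", {
  for (s in 1:20) {
    x <- withr::with_seed(400L + s, rnorm(1000))
    rec <- new_recording(matrix(x, 1L), 200)
    out <- bandpass(rec, 1, 40)
    e_before <- oracle_band_power(x, 200, c(60, 95))
    e_after <- oracle_band_power(out$signals[1L, ], 200, c(60, 95))
    expect_lt(e_after, e_before)
  }
})

test_that("segment_patches indexes, truncates, and inverts exactly", {
  sig <- matrix(seq_len(20), 2L, 10L, byrow = TRUE)
  rec <- new_recording(sig, 10)
  pt <- segment_patches(rec, 5L)
  expect_equal(dim(pt$patches), c(2L, 2L, 5L))
  for (c in 1:2) for (n in 1:2) for (p in 1:5)
    expect_equal(pt$patches[c, n, p], sig[c, (n - 1L) * 5L + p])
  # T = 11 -> N = 2, last sample dropped
  rec11 <- new_recording(matrix(1:11, 1L), 10)
  pt11 <- segment_patches(rec11, 5L)
  expect_equal(pt11$n_patches, 2L)
  expect_equal(as.numeric(pt11$patches[1L, , ]), as.numeric(rbind(1:5, 6:10)))
  expect_equal(unpatch(pt)$signals, sig, ignore_attr = TRUE)
  expect_error(segment_patches(new_recording(matrix(1:3, 1L), 10), 5L), "shorter")
})

test_that("subject split follows first-appearance order and partitions", {
  ids <- rep(0:122, each = 2L)
  sp <- split_subjects(ids, 80L, 20L)
  expect_length(unique(ids[sp$test]), 23L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(ids))
  sp5 <- split_subjects(c(4, 4, 2, 2, 9, 9, 0, 0, 7, 7), 3L, 1L)
  expect_length(unique(c(4, 4, 2, 2, 9, 9, 0, 0, 7, 7)[sp5$test]), 1L)
  expect_error(split_subjects(c(1, 2), 3L, 1L), "subjects")
})

test_that("trial split takes the stated per-subject prefix blocks", {
  ids <- rep(1:3, each = 15L)
  sp <- split_trials(ids, 5L, 5L)
  expect_length(sp$train, 15L)
  expect_length(sp$val, 15L)
  expect_length(sp$test, 15L)
  expect_equal(sp$train[1:5], 1:5)                        # subject 1 first five
  expect_equal(sp$val[1:5], 6:10)
  expect_equal(sp$test[1:5], 11:15)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(ids))
})

test_that("preprocess_trial chains resample, filter, and patching", {
  spec <- synthetic_task_spec(n_channels = 2L, n_classes = 2L, sfreq = 500,
                              duration = 2, seed = 8L)
  tr <- generate_trial(spec, 0L, 1L)
  cfg <- preprocess_config(target_sfreq = 250, band = c(1, 40),
                           apply_bandpass = TRUE, patch_size = 125L)
  pt <- preprocess_trial(tr, cfg)
  expect_equal(dim(pt$patches), c(2L, 4L, 125L))
  expect_equal(pt$sfreq, 250)
})
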