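test_that("background PSD slope tracks the 1/f exponent", {
  # averaged over 20 seeds of 10 s trials, fitted 1-40 Hz
  for (alpha in c(0, 1)) {
    spec <- synthetic_task_spec(n_channels = 1L, n_classes = 2L, sfreq = 128,
                                duration = 10, noise_exponent = alpha,
                                effect_size = 0, seed = 1L)
    slopes <- vapply(1:20, function(s) {
      tr <- generate_trial(spec, 0L, seed = 100L + s)
      oracle_psd_slope(tr$signals[1L, ], 128)
    }, numeric(1))
    expect_lt(abs(mean(slopes) - (-alpha)), 0.2)
  }
})

test_that("effect_size = 0 removes all class structure", {
  spec <- synthetic_task_spec(n_channels = 1L, n_classes = 2L, sfreq = 128,
                              duration = 2, class_bands = list(c(8, 13), c(25, 35)),
                              effect_size = 0, seed = 2L)
  bp <- function(cls) vapply(1:50, function(i) {
    tr <- generate_trial(spec, cls, seed = 1000L * cls + i)
    oracle_band_power(tr$signals[1L, ], 128, c(8, 13))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(bp(0L), bp(1L)))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixing is linear and identity mixing passes sources through", {
  M <- matrix(c(1, 0.4, -0.3, 2, 0.1, 0, 0.5, 0.5, 1), 3, 3)
  base <- synthetic_task_spec(n_channels = 3L, n_classes = 2L, sfreq = 128,
                              duration = 2, effect_size = 3, seed = 3L)
  mixed <- synthetic_task_spec(n_channels = 3L, n_classes = 2L, sfreq = 128,
                               duration = 2, effect_size = 3, mixing = M, seed = 3L)
  t0 <- generate_trial(base, 1L, seed = 7L)
  tM <- generate_trial(mixed, 1L, seed = 7L)
  expect_equal(tM$signals, M %*% t0$signals, tolerance = 1e-12)
})

test_that("band-power contrast grows monotonically with effect_size", {
  bp_at <- function(effect) {
    spec <- synthetic_task_spec(n_channels = 1L, n_classes = 2L, sfreq = 128,
                                duration = 4, class_bands = list(c(8, 13), c(25, 35)),
                                effect_size = effect, seed = 4L)
    mean(vapply(1:10, function(i) {
      tr <- generate_trial(spec, 0L, seed = 300L + i)
      oracle_band_power(tr$signals[1L, ], 128, c(8, 13)) /
        oracle_band_power(tr$signals[1L, ], 128, c(30, 50))
    }, numeric(1)))
  }
  ratios <- vapply(c(0, 2, 6), bp_at, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("generate_trial validates its domain", {
  spec <- synthetic_task_spec(n_channels = 2L, n_classes = 3L, sfreq = 128,
                              duration = 1)
  expect_error(generate_trial(spec, 3L, 1L), "class_id")
  expect_error(generate_trial(spec, -1L, 1L), "class_id")
  expect_error(synthetic_task_spec(n_channels = 2L, n_classes = 3L,
                                   sfreq = 128, duration = -1), "duration")
  expect_error(synthetic_task_spec(n_channels = 2L, n_classes = 2L, sfreq = 100,
                                   class_bands = list(c(10, 60), c(1, 5))),
               "class band")
})

test_that("make_dataset is balanced, reproducible, and order-independent", {
  spec <- synthetic_task_spec(n_channels = 2L, n_classes = 3L, sfreq = 64,
                              duration = 1, seed = 5L)
  ds <- make_dataset(spec, 10L, n_subjects = 4L)
  expect_equal(unname(table(ds$labels)), rep(10L, 3L), ignore_attr = TRUE)
  ds2 <- make_dataset(spec, 10L, n_subjects = 4L)
  expect_identical(lapply(ds$trials, `[[`, "signals"),
                   lapply(ds2$trials, `[[`, "signals"))
  # trial i does not depend on dataset size (per-trial RNG streams)
  ds_small <- make_dataset(spec, 2L, n_subjects = 2L)
  expect_identical(ds$trials[[3L]]$signals, ds_small$trials[[3L]]$signals)
  expect_error(make_dataset(spec, 1L, n_subjects = 10L), "n_subjects")
})

test_that("alpha band power separates a high-effect two-class task (AUC > 0.9)", {
  spec <- synthetic_task_spec(n_channels = 1L, n_classes = 2L, sfreq = 128,
                              duration = 2, class_bands = list(c(8, 13), c(25, 35)),
                              effect_size = 4, seed = 6L)
  ds <- make_dataset(spec, 50L, n_subjects = 1L)
  scores <- vapply(ds$trials, function(tr)
    oracle_band_power(tr$signals[1L, ], 128, c(8, 13)), numeric(1))
  auc <- oracle_rank_auc(scores, as.integer(ds$labels == 0L))
  expect_gt(auc, 0.9)
})

test_that("fixture archive round-trips exactly and validates its members", {
  spec <- synthetic_task_spec(n_channels = 2L, n_classes = 3L, sfreq = 64,
                              duration = 1, seed = 7L)
  ds <- make_dataset(spec, 1L, n_subjects = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  write_fixture(ds, path)
  back <- read_fixture(path)
  expect_identical(lapply(back$trials, `[[`, "signals"),
                   lapply(ds$trials, `[[`, "signals"))
  expect_identical(back$labels, ds$labels)
  expect_identical(back$subject_ids, ds$subject_ids)
  expect_equal(back$trials[[1L]]$sfreq, 64)
  expect_identical(back$trials[[1L]]$channel_names, ds$trials[[1L]]$channel_names)

  # missing member -> format error naming the field
  obj <- readRDS(path)
  obj$labels <- NULL
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(obj, bad)
  expect_error(read_fixture(bad), "labels")

  # empty dataset round-trips to empty
  empty <- structure(list(trials = list(), labels = integer(0),
                          subject_ids = integer(0), spec = spec),
                     class = "eeg_dataset")
  pe <- withr::local_tempfile(fileext = ".rds")
  write_fixture(empty, pe)
  back0 <- read_fixture(pe)
  expect_length(back0$trials, 0L)
})
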