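# Synthetic multichannel EEG with controllable class-conditional spectral
# structure: 1/f^alpha background plus narrow-band oscillatory power in a
# class-specific band, linearly mixed across channels.

#' Construct a raw EEG recording
#'
#' A recording is a C x T matrix of channel voltages (microvolts) plus its
#' sampling rate and channel names.
#'
#' @param signals numeric matrix, channels x samples.
#' @param sfreq sampling rate in Hz.
#' @param channel_names character vector of length `nrow(signals)`.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(signals, sfreq,
                          channel_names = sprintf("EEG%03d", seq_len(nrow(signals)))) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop_domain("`signals` must be a numeric channels x samples matrix")
  if (ncol(signals) < 1L) stop_domain("recording must have at least one sample")
  if (!all(is.finite(signals))) stop_domain("`signals` contains non-finite values")
  sfreq <- check_scalar(sfreq, "sfreq", lower = 1e-9)
  if (length(channel_names) != nrow(signals))
    stop_domain("channel_names length (%d) != number of channels (%d)",
                length(channel_names), nrow(signals))
  structure(list(signals = signals, sfreq = sfreq,
                 channel_names = as.character(channel_names)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signals), ncol(x$signals), x$sfreq,
              ncol(x$signals) / x$sfreq))
  invisible(x)
}

#' Specification of a synthetic EEG classification task
#'
#' Defines the generative model for labeled synthetic trials: every channel
#' source is 1/f^alpha background noise; a trial of class k additionally
#' carries band-limited stochastic oscillatory power in `class_bands[[k]]`,
#' with in-band power equal to `effect_size` times the background's in-band
#' power; sources are then mixed by the `mixing` matrix.
#'
#' @param n_channels number of EEG channels C.
#' @param n_classes number of emotion classes K (>= 2).
#' @param sfreq sampling rate in Hz.
#' @param duration trial duration in seconds.
#' @param noise_exponent alpha of the 1/f^alpha background PSD (1 is typical
#'   for resting EEG; 0 gives white noise).
#' @param class_bands list of K numeric pairs (low, high) in Hz, one band per
#'   class; defaults to canonical EEG bands spread over theta..gamma.
#' @param effect_size ratio of oscillation in-band power to background in-band
#'   power (0 removes the class signal entirely).
#' @param mixing C x C channel mixing matrix (identity by default).
#' @param seed integer seed stored with the spec; `make_dataset` derives one
#'   RNG stream per trial from it.
#' @return an object of class `eeg_task_spec`.
#' @export
synthetic_task_spec <- function(n_channels = 32L, n_classes = 9L, sfreq = 250,
                                duration = 10, noise_exponent = 1,
                                class_bands = NULL, effect_size = 3,
                                mixing = NULL, seed = 1L) {
  n_channels <- check_count(n_channels, "n_channels", 1L)
  n_classes <- check_count(n_classes, "n_classes", 2L)
  sfreq <- check_scalar(sfreq, "sfreq", lower = 1e-9)
  duration <- check_scalar(duration, "duration", lower = 1e-9)
  check_scalar(noise_exponent, "noise_exponent")
  check_scalar(effect_size, "effect_size", lower = 0)
  if (is.null(class_bands)) {
    # spread K bands over 4..min(45, 0.9*nyquist) Hz on a log grid
    hi <- min(45, 0.45 * sfreq)
    edges <- exp(seq(log(4), log(hi), length.out = n_classes + 1L))
    class_bands <- lapply(seq_len(n_classes), function(k) c(edges[k], edges[k + 1L]))
  }
  if (length(class_bands) != n_classes)
    stop_domain("need one class band per class (%d given, %d classes)",
                length(class_bands), n_classes)
  for (b in class_bands) {
    if (length(b) != 2L || !(0 < b[1] && b[1] < b[2] && b[2] < sfreq / 2))
      stop_domain("every class band must satisfy 0 < low < high < sfreq/2")
  }
  if (is.null(mixing)) mixing <- diag(n_channels)
  mixing <- as.matrix(mixing)
  if (!all(dim(mixing) == n_channels))
    stop_domain("`mixing` must be %d x %d", n_channels, n_channels)
  structure(list(n_channels = n_channels, n_classes = n_classes, sfreq = sfreq,
                 duration = duration, noise_exponent = noise_exponent,
                 class_bands = class_bands, effect_size = effect_size,
                 mixing = mixing, seed = as.integer(seed)),
            class = "eeg_task_spec")
}

# one channel of 1/f^alpha noise plus (optionally) band-limited stochastic
# oscillation, built in the frequency domain for exact spectral control;
# returns the time series and its exact background in-band power bookkeeping
synth_source <- function(n, sfreq, alpha, band = NULL, effect = 0) {
  kmax <- (n - 1L) %/% 2L                 # positive-frequency bins, Nyquist excluded
  f <- seq_len(kmax) * sfreq / n
  amp <- f^(-alpha / 2)
  amp <- amp / sqrt(sum(amp^2))           # unit total power before scaling
  phase <- stats::runif(kmax, 0, 2 * pi)
  coef <- amp * exp(1i * phase)
  rms <- 10                                # background RMS in microvolts
  scale <- rms * n / sqrt(2)               # mean(x^2) = 2*sum|X|^2/n^2
  coef <- coef * scale
  if (!is.null(band) && effect > 0) {
    sel <- which(f >= band[1] & f <= band[2])
    if (length(sel) == 0L)
      stop_domain("band (%g, %g) Hz resolves to no frequency bins at T=%d", band[1], band[2], n)
    p_bg <- 2 * sum(Mod(coef[sel])^2) / n^2      # exact background in-band power
    c_osc <- complex(real = stats::rnorm(length(sel)),
                     imaginary = stats::rnorm(length(sel)))
    # scale so realized oscillation in-band power is exactly effect * p_bg
    c_osc <- c_osc * sqrt(effect * p_bg * n^2 / (2 * sum(Mod(c_osc)^2)))
    coef[sel] <- coef[sel] + c_osc
  }
  spec <- complex(real = numeric(n))
  spec[1L + seq_len(kmax)] <- coef
  spec[n + 1L - seq_len(kmax)] <- Conj(coef)
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate one synthetic EEG trial of a given class
#'
#' @param spec an [synthetic_task_spec()] object.
#' @param class_id class label in 0..K-1.
#' @param seed integer seed; the trial is a deterministic function of
#'   (spec, class_id, seed).
#' @return an `eeg_recording`.
#' @export
generate_trial <- function(spec, class_id, seed) {
  stopifnot(inherits(spec, "eeg_task_spec"))
  if (!is.numeric(class_id) || length(class_id) != 1L ||
      class_id != round(class_id) || class_id < 0 || class_id >= spec$n_classes)
    stop_domain("class_id must be an integer in [0, %d)", spec$n_classes)
  n <- round(spec$duration * spec$sfreq)
  if (n < 2L) stop_domain("duration x sfreq must give at least 2 samples")
  band <- spec$class_bands[[class_id + 1L]]
  src <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(spec$n_channels), function(ch)
      synth_source(n, spec$sfreq, spec$noise_exponent, band, spec$effect_size),
      numeric(n)))
  })
  new_recording(spec$mixing %*% src, spec$sfreq)
}

#' Generate a balanced labeled synthetic dataset
#'
#' Labels cycle 0..K-1 over trial index and subjects are assigned round-robin,
#' so every subject sees a near-balanced class mix. Each trial draws from its
#' own RNG stream derived from (seed, trial index): datasets are reproducible
#' and trial i does not depend on how many trials are generated.
#'
#' @param spec an [synthetic_task_spec()].
#' @param n_trials_per_class trials per class.
#' @param n_subjects number of distinct subjects.
#' @param seed master seed (defaults to `spec$seed`).
#' @return an object of class `eeg_dataset` with fields `trials`, `labels`,
#'   `subject_ids`, `spec`.
#' @export
make_dataset <- function(spec, n_trials_per_class, n_subjects = 1L,
                         seed = spec$seed) {
  stopifnot(inherits(spec, "eeg_task_spec"))
  n_trials_per_class <- check_count(n_trials_per_class, "n_trials_per_class", 1L)
  n_subjects <- check_count(n_subjects, "n_subjects", 1L)
  n <- n_trials_per_class * spec$n_classes
  if (n_subjects > n)
    stop_domain("n_subjects (%d) exceeds total trials (%d)", n_subjects, n)
  labels <- as.integer((seq_len(n) - 1L) %% spec$n_classes)
  subject_ids <- as.integer((seq_len(n) - 1L) %% n_subjects)
  trials <- lapply(seq_len(n), function(i)
    generate_trial(spec, labels[i], derive_seed(seed, i)))
  structure(list(trials = trials, labels = labels, subject_ids = subject_ids,
                 spec = spec),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d trials, %d classes, %d subjects\n",
              length(x$trials), length(unique(x$labels)),
              length(unique(x$subject_ids))))
  invisible(x)
}

# ---- fixture archive ---------------------------------------------------------

fixture_fields <- c("signals", "labels", "subject_ids", "sfreq", "channel_names")

#' Write a labeled dataset to a compressed array archive
#'
#' The archive is a gzip-compressed R serialization of a named list with
#' members `signals` (trials x C x T double array, microvolts), `labels`,
#' `subject_ids`, `sfreq` and `channel_names`; floats round-trip exactly.
#'
#' @param ds an `eeg_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(ds, path) {
  stopifnot(inherits(ds, "eeg_dataset"))
  n <- length(ds$trials)
  if (n > 0L) {
    C <- nrow(ds$trials[[1L]]$signals); T <- ncol(ds$trials[[1L]]$signals)
    sig <- array(0, c(n, C, T))
    for (i in seq_len(n)) sig[i, , ] <- ds$trials[[i]]$signals
    sfreq <- ds$trials[[1L]]$sfreq
    ch <- ds$trials[[1L]]$channel_names
  } else {
    sig <- array(numeric(0), c(0L, 0L, 0L)); sfreq <- ds$spec$sfreq %||% NA_real_
    ch <- character(0)
  }
  saveRDS(list(signals = sig, labels = as.integer(ds$labels),
               subject_ids = as.integer(ds$subject_ids), sfreq = sfreq,
               channel_names = ch),
          path, compress = "gzip")
  invisible(path)
}

#' Read a labeled dataset from a fixture archive
#'
#' @param path file written by [write_fixture()].
#' @return an `eeg_dataset` (with `spec = NULL`).
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop_domain("fixture file not found: %s", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_domain("malformed archive: %s", conditionMessage(e)))
  if (!is.list(obj)) stop_domain("malformed archive: not a named-member archive")
  for (f in fixture_fields)
    if (!f %in% names(obj))
      stop_domain("malformed archive: missing required member `%s`", f)
  n <- dim(obj$signals)[1L]
  if (length(obj$labels) != n || length(obj$subject_ids) != n)
    stop_domain("malformed archive: labels/subject_ids length != number of trials")
  trials <- lapply(seq_len(n), function(i)
    new_recording(matrix(obj$signals[i, , ], dim(obj$signals)[2L], dim(obj$signals)[3L]),
                  obj$sfreq, obj$channel_names))
  structure(list(trials = trials, labels = as.integer(obj$labels),
                 subject_ids = as.integer(obj$subject_ids), spec = NULL),
            class = "eeg_dataset")
}
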