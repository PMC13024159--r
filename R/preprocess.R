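# Signal conditioning: polyphase resampling, zero-phase Butterworth band-pass,
# non-overlapping patch segmentation, and subject/trial split rules.

#' Preprocessing configuration
#'
#' @param target_sfreq resampling target in Hz (default 200).
#' @param band band-pass edges (low, high) in Hz, used when `apply_bandpass`.
#' @param apply_bandpass whether to band-pass filter (dataset-dependent: on for
#'   the 62-channel SEED-V-style preset, off for the 32-channel FACED-style one).
#' @param patch_size patch length P in samples (default 200, i.e. 1 s at 200 Hz).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_sfreq = 200, band = c(0.3, 75),
                              apply_bandpass = FALSE, patch_size = 200L) {
  target_sfreq <- check_scalar(target_sfreq, "target_sfreq", lower = 1e-9)
  patch_size <- check_count(patch_size, "patch_size", min = 2L)
  if (!is.null(band)) {
    if (length(band) != 2L || !(0 < band[1] && band[1] < band[2] &&
                                band[2] < target_sfreq / 2))
      stop_domain("band must satisfy 0 < low < high < target_sfreq/2")
  }
  structure(list(target_sfreq = target_sfreq, band = band,
                 apply_bandpass = isTRUE(apply_bandpass),
                 patch_size = patch_size),
            class = "preprocess_config")
}

# ---- resampling --------------------------------------------------------------

# best rational approximation p/q of x with bounded denominator
rational_ratio <- function(x, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  g <- gcd_int(best[1L], best[2L])
  c(best[1L] %/% g, best[2L] %/% g)
}

gcd_int <- function(a, b) { while (b != 0L) { t <- a %% b; a <- b; b <- t }; a }

# polyphase rational resampling of one signal by p/q with a Hamming-windowed
# sinc anti-aliasing filter (gain p, cutoff at the tighter of the two Nyquists)
resample_poly1 <- function(x, p, q, n_out) {
  if (p == q) return(x[seq_len(min(n_out, length(x)))])
  m <- max(p, q)
  half <- 10L * m
  k <- (-half):half
  fc <- 0.5 / m
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  h <- h * (0.54 + 0.46 * cos(pi * k / half))        # Hamming window
  h <- p * h / sum(h)
  up <- numeric(length(x) * p)
  up[seq(1L, by = p, length.out = length(x))] <- x
  y <- stats::convolve(up, rev(h), type = "open")    # full linear convolution
  idx <- half + 1L + (seq_len(n_out) - 1L) * q
  if (max(idx) > length(y)) y <- c(y, numeric(max(idx) - length(y)))
  y[idx]
}

#' Resample a recording to a target sampling rate
#'
#' Polyphase rational resampling with built-in anti-alias filtering; the output
#' has exactly `round(T * target_sfreq / sfreq)` samples per channel.
#'
#' @param rec an `eeg_recording`.
#' @param target_sfreq target rate in Hz.
#' @param upsample set TRUE to silence the warning when the target rate exceeds
#'   the source rate.
#' @return resampled `eeg_recording`.
#' @export
resample <- function(rec, target_sfreq, upsample = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  target_sfreq <- check_scalar(target_sfreq, "target_sfreq", lower = 1e-9)
  if (target_sfreq == rec$sfreq) return(rec)
  if (target_sfreq > rec$sfreq && !isTRUE(upsample))
    warning("target_sfreq above source rate; upsampling", call. = FALSE)
  pq <- rational_ratio(target_sfreq / rec$sfreq)
  n_out <- round(ncol(rec$signals) * target_sfreq / rec$sfreq)
  out <- t(apply(rec$signals, 1L, resample_poly1, p = pq[1L], q = pq[2L],
                 n_out = n_out))
  if (n_out == 1L) out <- matrix(out, nrow = nrow(rec$signals))
  new_recording(out, target_sfreq, rec$channel_names)
}

# ---- zero-phase Butterworth band-pass ---------------------------------------

# RBJ biquad coefficients (bilinear-transformed analog 2nd-order section)
biquad_coefs <- function(type, f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  cw <- cos(w0); sw <- sin(w0); al <- sw / (2 * Q)
  if (type == "lowpass") {
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
  } else {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  }
  a <- c(1 + al, -2 * cw, 1 - al)
  list(b = b / a[1L], a = a / a[1L])
}

# 4th-order Butterworth as a cascade of two biquads with the exact pole Qs
butter4_sections <- function(type, f0, fs) {
  lapply(c(1 / (2 * cos(pi / 8)), 1 / (2 * cos(3 * pi / 8))),
         function(Q) biquad_coefs(type, f0, fs, Q))
}

# direct-form-II-transposed biquad with steady-state initial conditions
biquad_apply <- function(x, bq) {
  b <- bq$b; a <- bq$a
  # lfilter_zi: solve (I - A) zi = B with companion-transpose A
  B <- c(b[2L] - a[2L] * b[1L], b[3L] - a[3L] * b[1L])
  A <- rbind(c(1 + a[2L], -1), c(a[3L], 1))
  zi <- solve(A, B) * x[1L]
  n <- length(x); y <- numeric(n)
  z1 <- zi[1L]; z2 <- zi[2L]
  for (i in seq_len(n)) {
    yi <- b[1L] * x[i] + z1
    z1 <- b[2L] * x[i] - a[2L] * yi + z2
    z2 <- b[3L] * x[i] - a[3L] * yi
    y[i] <- yi
  }
  y
}

# zero-phase (forward-backward) filtering through a biquad cascade with
# odd-reflection edge padding, scipy filtfilt style
filtfilt_cascade <- function(x, sections, padlen) {
  n <- length(x)
  padlen <- min(n - 1L, padlen)
  if (padlen > 0L) {
    pre <- 2 * x[1L] - x[(padlen + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    ext <- c(pre, x, post)
  } else ext <- x
  for (s in sections) ext <- biquad_apply(ext, s)
  ext <- rev(ext)
  for (s in sections) ext <- biquad_apply(ext, s)
  ext <- rev(ext)
  ext[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth high-pass at `low` Hz and a 4th-order
#' Butterworth low-pass at `high` Hz, each forward and backward (zero phase,
#' no group delay; effective magnitude response is the squared Butterworth).
#'
#' @param rec an `eeg_recording`.
#' @param low high-pass edge in Hz (removes baseline drift).
#' @param high low-pass edge in Hz (removes EMG/line noise).
#' @return filtered `eeg_recording`, same shape.
#' @export
bandpass <- function(rec, low, high) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sfreq
  if (!(0 < low && low < high && high < fs / 2))
    stop_domain("band (%g, %g) must satisfy 0 < low < high < sfreq/2 = %g",
                low, high, fs / 2)
  sections <- c(butter4_sections("highpass", low, fs),
                butter4_sections("lowpass", high, fs))
  padlen <- as.integer(min(3 * fs / low, ncol(rec$signals) - 1L))
  out <- t(apply(rec$signals, 1L, filtfilt_cascade, sections = sections,
                 padlen = padlen))
  new_recording(out, fs, rec$channel_names)
}

# ---- patch segmentation ------------------------------------------------------

#' Segment a recording into non-overlapping patches
#'
#' Reshapes the C x T signal matrix into a C x N x P tensor with N = floor(T/P)
#' non-overlapping windows; the trailing T mod P samples are discarded (no
#' zero-padding, which would inject spectral transients).
#'
#' @param rec an `eeg_recording`.
#' @param P patch size in samples.
#' @return an `eeg_patched` object with fields `patches` (C x N x P), `sfreq`,
#'   `n_patches`.
#' @export
segment_patches <- function(rec, P) {
  stopifnot(inherits(rec, "eeg_recording"))
  P <- check_count(P, "P", min = 2L)
  Tn <- ncol(rec$signals)
  if (Tn < P) stop_domain("trial has %d samples, shorter than patch size %d", Tn, P)
  N <- Tn %/% P
  C <- nrow(rec$signals)
  kept <- rec$signals[, seq_len(N * P), drop = FALSE]
  # patches[c, n, p] == signals[c, (n-1)*P + p]
  patches <- aperm(array(t(kept), c(P, N, C)), c(3L, 2L, 1L))
  structure(list(patches = patches, sfreq = rec$sfreq, n_patches = N),
            class = "eeg_patched")
}

#' Reassemble a patched trial into a recording
#'
#' Inverse of [segment_patches()] on the retained samples.
#'
#' @param pt an `eeg_patched`.
#' @param channel_names optional channel names.
#' @return an `eeg_recording` of length N*P.
#' @export
unpatch <- function(pt, channel_names = NULL) {
  stopifnot(inherits(pt, "eeg_patched"))
  d <- dim(pt$patches)
  sig <- t(matrix(aperm(pt$patches, c(3L, 2L, 1L)), d[2L] * d[3L], d[1L]))
  if (is.null(channel_names)) channel_names <- sprintf("EEG%03d", seq_len(d[1L]))
  new_recording(sig, pt$sfreq, channel_names)
}

# ---- splits ------------------------------------------------------------------

#' Split trials by subject
#'
#' Partitions trial indices by subject, ordering subjects by first appearance:
#' the first `n_train` subjects go to training, the next `n_val` to validation,
#' the remainder to test. No subject spans two partitions.
#'
#' @param subject_ids integer subject id per trial.
#' @param n_train,n_val numbers of training and validation subjects.
#' @return list of integer trial-index vectors `train`, `val`, `test`.
#' @export
split_subjects <- function(subject_ids, n_train, n_val) {
  n_train <- check_count(n_train, "n_train", 1L)
  n_val <- check_count(n_val, "n_val", 0L)
  subj <- unique(subject_ids)                      # order of first appearance
  if (n_train + n_val >= length(subj))
    stop_domain("need more than n_train + n_val = %d distinct subjects (got %d)",
                n_train + n_val, length(subj))
  grp <- list(train = subj[seq_len(n_train)],
              val = subj[n_train + seq_len(n_val)],
              test = subj[-seq_len(n_train + n_val)])
  lapply(grp, function(s) which(subject_ids %in% s))
}

#' Split trials by within-subject trial order
#'
#' For every subject independently: the first `n_train` of their trials (in
#' recording order) go to training, the next `n_val` to validation, the rest to
#' test — the within-subject protocol used for 15-trial-per-subject corpora
#' (first five train / next five validation / last five test).
#'
#' @inheritParams split_subjects
#' @return list of integer trial-index vectors `train`, `val`, `test`.
#' @export
split_trials <- function(subject_ids, n_train, n_val) {
  n_train <- check_count(n_train, "n_train", 1L)
  n_val <- check_count(n_val, "n_val", 0L)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (s in unique(subject_ids)) {
    idx <- which(subject_ids == s)
    if (length(idx) <= n_train + n_val)
      stop_domain("subject %s has %d trials, need more than n_train + n_val = %d",
                  format(s), length(idx), n_train + n_val)
    out$train <- c(out$train, idx[seq_len(n_train)])
    out$val <- c(out$val, idx[n_train + seq_len(n_val)])
    out$test <- c(out$test, idx[-seq_len(n_train + n_val)])
  }
  out
}

#' Run the full preprocessing pipeline on one recording
#'
#' Resample to `cfg$target_sfreq`, optionally band-pass, then segment into
#' patches of `cfg$patch_size` samples.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [preprocess_config()].
#' @return an `eeg_patched`.
#' @export
preprocess_trial <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  rec <- resample(rec, cfg$target_sfreq)
  if (cfg$apply_bandpass && !is.null(cfg$band))
    rec <- bandpass(rec, cfg$band[1L], cfg$band[2L])
  segment_patches(rec, cfg$patch_size)
}
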