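#' @keywords internal
"_PACKAGE"

# ---- small assertion helpers -------------------------------------------------

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_domain("`%s` must be a single integer >= %d (got %s)", name, min,
                paste(format(x), collapse = ","))
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_domain("`%s` must be a finite scalar in [%g, %g]", name, lower, upper)
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- deterministic RNG -------------------------------------------------------

# derive a 31-bit child seed from a parent seed and stream indices; a simple
# splitmix-like integer hash so per-trial streams are order-independent
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (v in idx) {
    h <- (h * 2654435.0 + as.numeric(v) + 40503.0) %% 2147483647
    h <- (h * 69069.0 + 1.0) %% 2147483647
  }
  as.integer(h %% 2147483587 + 1)
}

# ---- spectral utilities ------------------------------------------------------

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over 50%-overlapping Hann-windowed segments;
#' the standard nonparametric PSD estimator used for EEG band power.
#'
#' @param x numeric vector, the signal.
#' @param sfreq sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, sfreq, nperseg = min(256L, length(x))) {
  nperseg <- check_count(nperseg, "nperseg", min = 8L)
  n <- length(x)
  if (n < nperseg) stop_domain("signal shorter than nperseg")
  step <- nperseg %/% 2L
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- stats::fft(seg)[seq_len(nf)]
    p <- Mod(sp)^2 / (sfreq * u)
    # one-sided: double everything except DC and (for even nperseg) Nyquist
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * sfreq / nperseg, psd = acc / length(starts))
}

#' Mean band power of a signal
#'
#' @param x numeric vector.
#' @param sfreq sampling rate in Hz.
#' @param band length-2 numeric, (low, high) in Hz.
#' @param nperseg Welch segment length.
#' @return mean PSD over the band (power per Hz).
#' @export
band_power <- function(x, sfreq, band, nperseg = min(256L, length(x))) {
  p <- welch_psd(x, sfreq, nperseg)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  if (!any(sel)) stop_domain("band (%g, %g) Hz contains no PSD bins", band[1], band[2])
  mean(p$psd[sel])
}

# ---- tiny tensor helpers -----------------------------------------------------

# batched outer product: u (B x n), v (B x m) -> (B x n x m)
batched_outer <- function(u, v) {
  B <- nrow(u); n <- ncol(u); m <- ncol(v)
  array(u, c(B, n, m)) * aperm(array(v, c(B, m, n)), c(1L, 3L, 2L))
}

# broadcast a (B x n) matrix along a trailing dim of size m -> (B x n x m)
bc3 <- function(u, m) array(u, c(dim(u), m))

# sum over dim 2 of a (B x n x m) array -> (B x m)
sum_mid <- function(a) {
  d <- dim(a)
  colSums(aperm(a, c(2L, 1L, 3L)), dims = 1L)
}
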