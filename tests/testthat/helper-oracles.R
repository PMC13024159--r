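# Independent numerical oracles. These deliberately re-derive quantities from
# first principles (raw FFTs, dense matrices, definition-level metrics) and
# never call the package code paths they are used to check.

# Welch-style PSD with plain rectangular segments and raw fft(); independent
# of eegmamba::welch_psd
oracle_psd <- function(x, sfreq, nseg = 256L) {
  starts <- seq(1L, length(x) - nseg + 1L, by = nseg %/% 2L)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- seg - mean(seg)
    sp <- Mod(fft(seg)[seq_len(nf)])^2 / (nseg * sfreq)
    sp[2:(nf - 1L)] <- 2 * sp[2:(nf - 1L)]
    acc <- acc + sp
  }
  list(freq = (seq_len(nf) - 1L) * sfreq / nseg, psd = acc / length(starts))
}

# least-squares log-log PSD slope between lo and hi Hz
oracle_psd_slope <- function(x, sfreq, lo = 1, hi = 40) {
  p <- oracle_psd(x, sfreq)
  sel <- p$freq >= lo & p$freq <= hi & p$psd > 0
  unname(coef(lm(log(p$psd[sel]) ~ log(p$freq[sel])))[2L])
}

# rank (Mann-Whitney) AUC of scores for labels in {0, 1}
oracle_rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# raw-fft band power (mean one-sided periodogram over band), no Welch
oracle_band_power <- function(x, sfreq, band) {
  n <- length(x)
  nf <- n %/% 2L + 1L
  p <- Mod(fft(x - mean(x))[seq_len(nf)])^2 / (n * sfreq)
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  f <- (seq_len(nf) - 1L) * sfreq / n
  mean(p[f >= band[1] & f <= band[2]])
}

# dense L x L causal operator equivalent to the selective scan (O(L^2) brute
# force): y = M %*% x per feature column
oracle_ssd_dense <- function(delta, A, B_seq, C_seq, D_skip) {
  L <- length(delta)
  M <- matrix(0, L, L)
  for (t in seq_len(L)) {
    for (s in seq_len(t)) {
      dec <- if (s < t) prod(exp(delta[(s + 1L):t] * A)) else 1
      M[t, s] <- sum(C_seq[t, ] * B_seq[s, ]) * delta[s] * dec
    }
    M[t, t] <- M[t, t] + D_skip
  }
  M
}

# definition-level metrics from a confusion table, independent of
# compute_metrics internals
oracle_metrics <- function(y_true, y_pred, K) {
  cm <- table(factor(y_true, levels = 0:(K - 1L)),
              factor(y_pred, levels = 0:(K - 1L)))
  cm <- unclass(cm)
  rec <- diag(cm) / rowSums(cm)
  prec <- diag(cm) / colSums(cm)
  prec[is.nan(prec)] <- 0
  n <- length(y_true)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  sup <- rowSums(cm)
  list(balacc = mean(rec[sup > 0]) * 100,
       kappa = (po - pe) / (1 - pe) * 100,
       wf1 = sum((f1 * sup)[sup > 0]) / n * 100)
}

# central finite difference of f at x[i]
fd_partial <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}
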