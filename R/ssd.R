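# Reference selective state-space (SSD / Mamba2-style) scan.
#
# Per head, the discretized recurrence with zero-order-hold decay and Euler
# input discretization is
#
#   S_t = exp(dt_t * A) * S_{t-1} + dt_t * B_t x_t^T        (S in R^{S x E})
#   y_t = S_t^T C_t + D_skip . x_t
#
# with scalar per-head decay A < 0 and data-dependent per-step dt_t, B_t, C_t
# (the "selectivity"). The sequential loop below is the normative
# implementation; the dense O(L^2) causal operator serves as its oracle in the
# tests, and the batched version used inside the network must agree with it.

#' Reference selective scan over one sequence
#'
#' @param x L x E matrix of inputs (E = head dimension).
#' @param delta length-L positive step sizes.
#' @param A scalar decay, strictly negative.
#' @param B_seq,C_seq L x S matrices of per-step input/output maps.
#' @param D_skip scalar or length-E skip connection gain.
#' @param d_state state size S (defaults to `ncol(B_seq)`).
#' @return L x E output matrix; strictly causal in the row index.
#' @export
ssd_scan_reference <- function(x, delta, A, B_seq, C_seq, D_skip = 0,
                               d_state = ncol(B_seq)) {
  x <- as.matrix(x)
  L <- nrow(x); E <- ncol(x)
  stopifnot(length(delta) == L, nrow(B_seq) == L, nrow(C_seq) == L,
            ncol(B_seq) == d_state, ncol(C_seq) == d_state)
  if (!all(is.finite(x)) || !all(is.finite(delta)))
    stop_domain("non-finite inputs to ssd_scan_reference")
  if (is.finite(A) && A >= 0) stop_domain("A must be strictly negative")
  if (length(D_skip) == 1L) D_skip <- rep(D_skip, E)
  S <- matrix(0, d_state, E)
  y <- matrix(0, L, E)
  for (t in seq_len(L)) {
    abar <- exp(delta[t] * A)                  # A -> -Inf gives abar = 0
    S <- abar * S + delta[t] * tcrossprod(B_seq[t, ], x[t, ])
    if (!all(is.finite(S)))
      stop_domain("state overflow at step %d of the selective scan", t)
    y[t, ] <- crossprod(S, C_seq[t, ]) + D_skip * x[t, ]
  }
  y
}

# dimension-safe slices (R drops dims on single-index slicing)
slice2 <- function(a, t) {           # (B, L, S)[, t, ] -> B x S
  d <- dim(a); m <- a[, t, , drop = FALSE]; dim(m) <- c(d[1L], d[3L]); m
}
slice3 <- function(a, t, h) {        # (B, L, H, E)[, t, h, ] -> B x E
  d <- dim(a); m <- a[, t, h, , drop = FALSE]; dim(m) <- c(d[1L], d[4L]); m
}
slice_state <- function(st, h, t) {  # (B, S, E, H, L)[, , , h, t] -> B x S x E
  d <- dim(st); a <- st[, , , h, t, drop = FALSE]; dim(a) <- d[1:3]; a
}

# batched multi-head scan used inside the Mamba block.
#   x: (B, L, H, E)   dt: (B, L, H)   A: length H (negative)
#   Bseq, Cseq: (B, L, S)  shared across heads (Mamba2 convention)
#   D_skip: (H, E)
# returns list(y = (B,L,H,E), states kept for backward)
ssd_scan_batched_fw <- function(x, dt, A, Bseq, Cseq, D_skip, keep_states = TRUE) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; H <- d[3L]; E <- d[4L]
  S <- dim(Bseq)[3L]
  y <- array(0, c(B, L, H, E))
  states <- if (keep_states) array(0, c(B, S, E, H, L)) else NULL
  for (h in seq_len(H)) {
    Sh <- array(0, c(B, S, E))
    Dh <- matrix(rep(D_skip[h, ], each = B), B, E)
    for (t in seq_len(L)) {
      dth <- dt[, t, h]
      abar <- exp(dth * A[h])                            # length B
      xt <- slice3(x, t, h)
      Sh <- Sh * array(abar, c(B, S, E)) +
        batched_outer(dth * slice2(Bseq, t), xt)
      y[, t, h, ] <- sum_mid(Sh * bc3(slice2(Cseq, t), E)) + Dh * xt
      if (keep_states) states[, , , h, t] <- Sh
    }
  }
  if (!all(is.finite(y))) stop_domain("non-finite output in selective scan")
  list(y = y, states = states)
}

# backward of the batched scan; returns gradients for x, dt, A, Bseq, Cseq,
# D_skip given dy
ssd_scan_batched_bw <- function(cache, dy) {
  x <- cache$x; dt <- cache$dt; A <- cache$A
  Bseq <- cache$Bseq; Cseq <- cache$Cseq; D_skip <- cache$D_skip
  states <- cache$states
  d <- dim(x); B <- d[1L]; L <- d[2L]; H <- d[3L]; E <- d[4L]
  S <- dim(Bseq)[3L]
  dx <- array(0, c(B, L, H, E))
  ddt <- array(0, c(B, L, H))
  dA <- numeric(H)
  dB <- array(0, c(B, L, S))
  dC <- array(0, c(B, L, S))
  dD <- matrix(0, H, E)
  for (h in seq_len(H)) {
    dSh <- array(0, c(B, S, E))          # accumulated dL/dS_t
    Dh <- matrix(rep(D_skip[h, ], each = B), B, E)
    for (t in rev(seq_len(L))) {
      dyt <- slice3(dy, t, h)
      xt <- slice3(x, t, h)
      St <- slice_state(states, h, t)
      dyt_bc <- aperm(bc3(dyt, S), c(1L, 3L, 2L))        # B x S x E
      # y_t = sum_s S_t[s,] C_t[s] + D . x_t
      dC[, t, ] <- dC[, t, ] + sum_3(St * dyt_bc)
      dD[h, ] <- dD[h, ] + colSums(dyt * xt)
      dx[, t, h, ] <- slice3(dx, t, h) + dyt * Dh
      dSh <- dSh + bc3(slice2(Cseq, t), E) * dyt_bc
      # S_t = abar_t S_{t-1} + dt_t B_t x_t^T
      dth <- dt[, t, h]
      abar <- exp(dth * A[h])
      Sprev <- if (t > 1L) slice_state(states, h, t - 1L) else array(0, c(B, S, E))
      dabar <- rowSums(matrix(dSh * Sprev, B, S * E))
      Bt <- slice2(Bseq, t)
      ddt[, t, h] <- dabar * A[h] * abar +
        rowSums(matrix(dSh * batched_outer(Bt, xt), B, S * E))
      dA[h] <- dA[h] + sum(dabar * dth * abar)
      dB[, t, ] <- dB[, t, ] +
        dth * sum_3(dSh * aperm(bc3(xt, S), c(1L, 3L, 2L)))
      dx[, t, h, ] <- slice3(dx, t, h) + sum_mid(dSh * bc3(dth * Bt, E))
      dSh <- dSh * array(abar, c(B, S, E))               # flows to S_{t-1}
    }
  }
  list(dx = dx, ddt = ddt, dA = dA, dB = dB, dC = dC, dD = dD)
}

# sum over dim 3 of a (B x n x m) array -> (B x n)
sum_3 <- function(a) {
  d <- dim(a)
  matrix(rowSums(matrix(a, d[1L] * d[2L], d[3L])), d[1L], d[2L])
}
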