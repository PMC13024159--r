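# Classification head: global multi-head self-attention recalibration over all
# channel-time tokens (pre-norm, residual), then a three-layer MLP with ELU and
# dropout, trained with label-smoothing cross-entropy.

init_head_params <- function(cfg) {
  D <- cfg$embed_dim
  p <- list()
  if (cfg$use_attention) {
    r <- function(n) stats::rnorm(n, 0, 1 / sqrt(D))
    p$attn_ln_g <- rep(1, D); p$attn_ln_b <- numeric(D)
    p$Wq <- matrix(r(D * D), D, D); p$bq <- numeric(D)
    p$Wk <- matrix(r(D * D), D, D); p$bk <- numeric(D)
    p$Wv <- matrix(r(D * D), D, D); p$bv <- numeric(D)
    p$Wo <- matrix(r(D * D), D, D); p$bo <- numeric(D)
  }
  nin <- cfg$n_channels * cfg$n_patches * D
  widths <- c(nin, cfg$mlp_hidden, cfg$n_classes)
  p$mlp <- lapply(seq_len(length(widths) - 1L), function(i) {
    list(W = matrix(stats::rnorm(widths[i] * widths[i + 1L], 0,
                                 sqrt(2 / widths[i])), widths[i], widths[i + 1L]),
         b = numeric(widths[i + 1L]))
  })
  p
}

#' Global attention recalibration over all channel-time tokens
#'
#' Flattens the latent tensor to B x (C*N) x D tokens and applies pre-norm
#' multi-head self-attention with a residual connection. No positional
#' encoding is re-added (positions were injected at the embedding).
#'
#' @param h B x C x N x D latent tensor.
#' @param params head parameter list.
#' @param cfg model configuration (`n_attn_heads`).
#' @param keep_cache keep intermediates for backprop.
#' @return list(out = B x C x N x D, cache).
#' @export
global_recalibrate <- function(h, params, cfg, keep_cache = TRUE) {
  d <- dim(h)
  if (length(d) != 4L) stop_domain("latent tensor must be B x C x N x D")
  B <- d[1L]; L <- d[2L] * d[3L]; D <- d[4L]
  Hh <- cfg$n_attn_heads
  if (D %% Hh != 0L) stop_domain("embed_dim %d not divisible by n_attn_heads %d", D, Hh)
  hd <- D %/% Hh
  tok <- array(h, c(B, L, D))
  ln <- layernorm_fw(matrix(tok, B * L, D), params$attn_ln_g, params$attn_ln_b)
  q <- linear_fw(ln$out, params$Wq, params$bq)
  k <- linear_fw(ln$out, params$Wk, params$bk)
  v <- linear_fw(ln$out, params$Wv, params$bv)
  att_out <- matrix(0, B * L, D)
  att_cache <- if (keep_cache) vector("list", B)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(L) - 1L)       # rows of token (b, l)
    pc <- if (keep_cache) vector("list", Hh)
    for (hh in seq_len(Hh)) {
      cols <- (hh - 1L) * hd + seq_len(hd)
      Qm <- q$out[rows, cols, drop = FALSE]
      Km <- k$out[rows, cols, drop = FALSE]
      Vm <- v$out[rows, cols, drop = FALSE]
      Sm <- tcrossprod(Qm, Km) / sqrt(hd)
      P <- softmax_rows(Sm)
      att_out[rows, cols] <- P %*% Vm
      if (keep_cache) pc[[hh]] <- list(Q = Qm, K = Km, V = Vm, P = P)
    }
    if (keep_cache) att_cache[[b]] <- pc
  }
  o <- linear_fw(att_out, params$Wo, params$bo)
  out <- h + array(o$out, d)
  list(out = out,
       cache = if (keep_cache) list(ln = ln, q = q, k = k, v = v, o = o,
                                    att = att_cache, dims = d, hd = hd))
}

global_recalibrate_bw <- function(cache, dout, cfg) {
  d <- cache$dims
  B <- d[1L]; L <- d[2L] * d[3L]; D <- d[4L]
  Hh <- cfg$n_attn_heads; hd <- cache$hd
  dm <- matrix(dout, B * L, D)
  ob <- linear_bw(cache$o$cache, dm)
  datt <- ob$dx
  dq <- matrix(0, B * L, D); dk <- matrix(0, B * L, D); dv <- matrix(0, B * L, D)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(L) - 1L)
    for (hh in seq_len(Hh)) {
      cols <- (hh - 1L) * hd + seq_len(hd)
      cc <- cache$att[[b]][[hh]]
      dO <- datt[rows, cols, drop = FALSE]
      dP <- tcrossprod(dO, cc$V)
      dV <- crossprod(cc$P, dO)
      # softmax rows backward
      dS <- cc$P * (dP - rowSums(dP * cc$P))
      dQ <- dS %*% cc$K / sqrt(hd)
      dK <- crossprod(dS, cc$Q) / sqrt(hd)
      dq[rows, cols] <- dQ; dk[rows, cols] <- dK; dv[rows, cols] <- dV
    }
  }
  qb <- linear_bw(cache$q$cache, dq)
  kb <- linear_bw(cache$k$cache, dk)
  vb <- linear_bw(cache$v$cache, dv)
  lb <- layernorm_bw(cache$ln$cache, qb$dx + kb$dx + vb$dx)
  dh <- dout + array(lb$dx, d)               # residual path
  list(grads = list(attn_ln_g = lb$dg, attn_ln_b = lb$db,
                    Wq = qb$dW, bq = qb$db, Wk = kb$dW, bk = kb$db,
                    Wv = vb$dW, bv = vb$db, Wo = ob$dW, bo = ob$db),
       dh = dh)
}

#' MLP classifier forward pass
#'
#' Flattens B x C x N x D to B x (C*N*D) and applies three linear layers with
#' ELU activations and dropout between them, emitting K logits.
#'
#' @param h B x C x N x D latent tensor.
#' @param params head parameter list with `mlp`.
#' @param cfg model configuration (`mlp_dropout` per hidden layer).
#' @param training dropout is active only in training mode.
#' @param keep_cache keep intermediates for backprop.
#' @return list(out = B x K logits, cache).
#' @export
mlp_head_fw <- function(h, params, cfg, training = FALSE, keep_cache = TRUE) {
  d <- dim(h)
  x <- matrix(h, d[1L], prod(d[-1L]))        # flatten per trial
  layers <- params$mlp
  n <- length(layers)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    lf <- linear_fw(x, layers[[i]]$W, layers[[i]]$b)
    if (i < n) {
      af <- elu_fw(lf$out)
      dp <- dropout_fw(af$out, cfg$mlp_dropout[min(i, length(cfg$mlp_dropout))],
                       training)
      x <- dp$out
      caches[[i]] <- list(lin = lf, act = af$cache, drop = dp$cache)
    } else {
      x <- lf$out
      caches[[i]] <- list(lin = lf)
    }
  }
  list(out = x, cache = if (keep_cache) list(layers = caches, dims = d))
}

mlp_head_bw <- function(cache, dout) {
  caches <- cache$layers
  n <- length(caches)
  g <- vector("list", n)
  dx <- dout
  for (i in rev(seq_len(n))) {
    if (i < n) {
      dx <- dropout_bw(caches[[i]]$drop, dx)
      dx <- elu_bw(caches[[i]]$act, dx)
    }
    lb <- linear_bw(caches[[i]]$lin$cache, dx)
    g[[i]] <- list(W = lb$dW, b = lb$db)
    dx <- lb$dx
  }
  list(grads = g, dh = array(dx, cache$dims))
}

#' Label-smoothing cross-entropy loss
#'
#' loss = -(1/B) sum_b sum_i [(1-eps) y_i + eps/K] log p_i with p = softmax of
#' the logits; eps = 0 recovers plain cross-entropy.
#'
#' @param logits B x K matrix.
#' @param y integer labels in 0..K-1.
#' @param eps smoothing factor in [0, 1).
#' @return list(loss = scalar, probs = B x K, dlogits = B x K gradient).
#' @export
label_smoothing_ce <- function(logits, y, eps = 0.1) {
  if (eps < 0 || eps >= 1) stop_domain("smoothing eps must be in [0, 1)")
  B <- nrow(logits); K <- ncol(logits)
  if (length(y) != B) stop_domain("labels length != batch size")
  if (any(y < 0 | y >= K)) stop_domain("labels must lie in [0, %d)", K)
  p <- softmax_rows(logits)
  q <- matrix(eps / K, B, K)
  q[cbind(seq_len(B), y + 1L)] <- q[cbind(seq_len(B), y + 1L)] + (1 - eps)
  logp <- logits - apply(logits, 1L, max)
  logp <- logp - log(rowSums(exp(logp)))
  loss <- -mean(rowSums(q * logp))
  list(loss = loss, probs = p, dlogits = (p - q) / B)
}

#' Convert logits to a prediction object
#'
#' @param logits B x K matrix.
#' @return list with `logits`, `probabilities` (rows sum to 1) and
#'   `predicted_class` (0-based argmax).
#' @export
as_prediction <- function(logits) {
  p <- softmax_rows(logits)
  list(logits = logits, probabilities = p,
       predicted_class = max.col(p, ties.method = "first") - 1L)
}
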