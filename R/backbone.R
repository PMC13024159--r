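# Decoupled spatial-temporal backbone: a stack of bidirectional Mamba2-style
# selective-scan blocks, each operating on a serialization ("view") of the
# B x C x N x D latent tensor chosen per layer:
#
#   spatial_first : token l = (n-1)*C + c  — channels in the inner loop, so
#                   the scan sweeps the whole montage at time n before moving
#                   to n+1 (instantaneous functional connectivity);
#   temporal_first: token l = (c-1)*N + n  — patches in the inner loop, so the
#                   scan tracks one channel's full time course before the next
#                   (independent per-channel dynamics).
#
# Because plain SSM scans are causal, every block is applied bidirectionally:
# out = block(v) + flip(block(flip(v))) with shared parameters.

LAYOUTS <- c("spatial_first", "temporal_first")

#' Serialize a latent tensor into a token sequence
#'
#' @param h B x C x N x D array.
#' @param layout `"spatial_first"` (channel index fastest) or
#'   `"temporal_first"` (patch index fastest).
#' @return a `sequence_view`: list(tokens = B x L x D, layout, c_dim, n_dim).
#' @export
unfold_view <- function(h, layout = c("spatial_first", "temporal_first")) {
  layout <- match.arg(layout)
  d <- dim(h)
  if (length(d) != 4L) stop_domain("latent tensor must be B x C x N x D")
  tokens <- if (layout == "spatial_first") {
    array(h, c(d[1L], d[2L] * d[3L], d[4L]))
  } else {
    array(aperm(h, c(1L, 3L, 2L, 4L)), c(d[1L], d[2L] * d[3L], d[4L]))
  }
  structure(list(tokens = tokens, layout = layout, c_dim = d[2L], n_dim = d[3L]),
            class = "sequence_view")
}

#' Invert a sequence view back into the latent tensor
#'
#' Exact inverse permutation of [unfold_view()].
#'
#' @param v a `sequence_view`.
#' @return B x C x N x D array.
#' @export
fold_view <- function(v) {
  stopifnot(inherits(v, "sequence_view"))
  d <- dim(v$tokens)
  if (d[2L] != v$c_dim * v$n_dim)
    stop_domain("sequence length %d != c_dim * n_dim = %d", d[2L],
                v$c_dim * v$n_dim)
  if (v$layout == "spatial_first") {
    array(v$tokens, c(d[1L], v$c_dim, v$n_dim, d[3L]))
  } else {
    aperm(array(v$tokens, c(d[1L], v$n_dim, v$c_dim, d[3L])), c(1L, 3L, 2L, 4L))
  }
}

#' Reverse the token axis of a sequence view
#'
#' @param v a `sequence_view` (or a B x L x D array).
#' @return same type, token order reversed.
#' @export
flip_tokens <- function(v) {
  if (inherits(v, "sequence_view")) {
    v$tokens <- v$tokens[, rev(seq_len(dim(v$tokens)[2L])), , drop = FALSE]
    v
  } else {
    v[, rev(seq_len(dim(v)[2L])), , drop = FALSE]
  }
}

# ---- Mamba block -------------------------------------------------------------

init_mamba_params <- function(cfg) {
  D <- cfg$embed_dim; E <- cfg$expand * D
  H <- cfg$n_ssd_heads; S <- cfg$d_state
  r <- function(n, sd) stats::rnorm(n, 0, sd)
  # dt bias inverts softplus so initial dt spans [dt_min, dt_max] log-uniformly
  dt0 <- exp(stats::runif(H, log(cfg$dt_min), log(cfg$dt_max)))
  list(
    in_proj_W = matrix(r(D * 2L * E, 1 / sqrt(D)), D, 2L * E),
    in_proj_b = numeric(2L * E),
    conv_w = matrix(r(E * cfg$conv_kernel_seq, 1 / sqrt(cfg$conv_kernel_seq)),
                    E, cfg$conv_kernel_seq),
    conv_b = numeric(E),
    dt_W = matrix(r(E * H, 1 / sqrt(E)), E, H),
    dt_b = log(expm1(dt0)),
    B_W = matrix(r(E * S, 1 / sqrt(E)), E, S),
    C_W = matrix(r(E * S, 1 / sqrt(E)), E, S),
    A_log = log(stats::runif(H, cfg$a_init[1L], cfg$a_init[2L])),
    D_skip = rep(1, E),
    out_proj_W = matrix(r(E * D, 0.02), E, D),
    out_proj_b = numeric(D)
  )
}

#' Forward pass of one Mamba2-style block
#'
#' Input projection to an expanded width plus a gate branch, short causal
#' depthwise convolution, SiLU, data-dependent step size / input map / output
#' map (the selective part), multi-head SSD scan, SiLU-gated multiplication,
#' and output projection back to D.
#'
#' @param tokens B x L x D array.
#' @param params block parameter list (see `init_mamba_params`).
#' @param cfg model configuration.
#' @param keep_cache keep intermediates for the backward pass.
#' @return list(out = B x L x D, cache).
#' @export
mamba_block_fw <- function(tokens, params, cfg, keep_cache = TRUE) {
  d <- dim(tokens); B <- d[1L]; L <- d[2L]; D <- d[3L]
  E <- cfg$expand * D; H <- cfg$n_ssd_heads; hd <- E %/% H
  if (E %% H != 0L) stop_domain("expanded width %d not divisible by n_ssd_heads %d", E, H)
  tm <- matrix(tokens, B * L, D)
  ip <- linear_fw(tm, params$in_proj_W, params$in_proj_b)
  x0 <- array(ip$out[, seq_len(E)], c(B, L, E))
  z <- array(ip$out[, E + seq_len(E)], c(B, L, E))
  cv <- causal_dwconv_fw(x0, params$conv_w, params$conv_b)
  ac <- silu_fw(cv$out)
  xa <- ac$out                                          # B x L x E
  xm <- matrix(xa, B * L, E)
  dt_lin <- linear_fw(xm, params$dt_W, params$dt_b)
  dt_sp <- softplus(dt_lin$out)
  clamped_lo <- dt_sp < cfg$dt_min
  clamped_hi <- dt_sp > cfg$dt_max
  dt <- array(pmin(pmax(dt_sp, cfg$dt_min), cfg$dt_max), c(B, L, H))
  Bl <- linear_fw(xm, params$B_W)
  Cl <- linear_fw(xm, params$C_W)
  Bseq <- array(Bl$out, c(B, L, cfg$d_state))
  Cseq <- array(Cl$out, c(B, L, cfg$d_state))
  A <- -exp(params$A_log)
  xh <- array(xa, c(B, L, hd, H))                       # e = (h-1)*hd + j, j fastest
  xh <- aperm(xh, c(1L, 2L, 4L, 3L))                    # B x L x H x hd
  Dsk <- matrix(params$D_skip, hd, H)                   # column h = head h gains
  scan <- ssd_scan_batched_fw(xh, dt, A, Bseq, Cseq, t(Dsk), keep_states = keep_cache)
  y <- array(aperm(scan$y, c(1L, 2L, 4L, 3L)), c(B, L, E))
  gz <- silu_fw(z)
  yg <- y * gz$out
  op <- linear_fw(matrix(yg, B * L, E), params$out_proj_W, params$out_proj_b)
  out <- array(op$out, c(B, L, D))
  cache <- if (keep_cache) list(
    ip = ip, cv = cv, ac = ac, dt_lin = dt_lin, Bl = Bl, Cl = Cl,
    scan = list(x = xh, dt = dt, A = A, Bseq = Bseq, Cseq = Cseq,
                D_skip = t(Dsk), states = scan$states),
    clamped = clamped_lo | clamped_hi, dt_sp = dt_sp,
    y = y, z = z, gz = gz, yg = yg, op = op,
    dims = c(B = B, L = L, D = D, E = E, H = H, hd = hd)
  ) else NULL
  list(out = out, cache = cache)
}

mamba_block_bw <- function(cache, dout, params, cfg) {
  dm <- cache$dims
  B <- dm["B"]; L <- dm["L"]; D <- dm["D"]; E <- dm["E"]; H <- dm["H"]; hd <- dm["hd"]
  ob <- linear_bw(cache$op$cache, matrix(dout, B * L, D))
  dyg <- array(ob$dx, c(B, L, E))
  dy <- dyg * cache$gz$out
  dz <- silu_bw(cache$gz$cache, dyg * cache$y)
  dyh <- aperm(array(dy, c(B, L, hd, H)), c(1L, 2L, 4L, 3L))
  sb <- ssd_scan_batched_bw(cache$scan, dyh)
  dxa_scan <- array(aperm(sb$dx, c(1L, 2L, 4L, 3L)), c(B, L, E))
  # dt path: clamp passes gradient only inside the band; softplus derivative
  ddt_flat <- matrix(sb$ddt, B * L, H)
  ddt_flat[cache$clamped] <- 0
  ddt_raw <- ddt_flat * (1 - exp(-cache$dt_sp))         # d softplus = sigmoid(raw)
  dtb <- linear_bw(cache$dt_lin$cache, ddt_raw)
  Bb <- linear_bw(cache$Bl$cache, matrix(sb$dB, B * L, cfg$d_state))
  Cb <- linear_bw(cache$Cl$cache, matrix(sb$dC, B * L, cfg$d_state))
  dxm <- dtb$dx + Bb$dx + Cb$dx + matrix(dxa_scan, B * L, E)
  dxc <- silu_bw(cache$ac$cache, array(dxm, c(B, L, E)))
  cb <- causal_dwconv_bw(cache$cv$cache, dxc)
  dip <- cbind(matrix(cb$dx, B * L, E), matrix(dz, B * L, E))
  ib <- linear_bw(cache$ip$cache, dip)
  dA <- sb$dA                                           # A = -exp(A_log)
  dA_log <- -dA * exp(params$A_log)
  dDsk_mat <- sb$dD                                     # H x hd
  grads <- list(
    in_proj_W = ib$dW, in_proj_b = ib$db,
    conv_w = cb$dw, conv_b = cb$db,
    dt_W = dtb$dW, dt_b = dtb$db,
    B_W = Bb$dW, C_W = Cb$dW,
    A_log = dA_log,
    D_skip = as.numeric(matrix(t(dDsk_mat), E, 1L)),
    out_proj_W = ob$dW, out_proj_b = ob$db
  )
  list(grads = grads, dx = array(ib$dx, c(B, L, D)))
}

#' Bidirectional application of a shape-preserving block
#'
#' out = block(v) + flip(block(flip(v))); one parameter set serves both
#' directions, so the composite is equivariant under token reversal.
#'
#' @param tokens B x L x D array.
#' @param params,cfg block parameters and model configuration.
#' @param keep_cache keep intermediates for backprop.
#' @return list(out, cache).
#' @export
bidirectional_fw <- function(tokens, params, cfg, keep_cache = TRUE) {
  fwd <- mamba_block_fw(tokens, params, cfg, keep_cache)
  rev_in <- flip_tokens(tokens)
  bwd <- mamba_block_fw(rev_in, params, cfg, keep_cache)
  out <- fwd$out + flip_tokens(bwd$out)
  list(out = out, cache = if (keep_cache) list(fwd = fwd$cache, bwd = bwd$cache))
}

bidirectional_bw <- function(cache, dout, params, cfg) {
  g1 <- mamba_block_bw(cache$fwd, dout, params, cfg)
  g2 <- mamba_block_bw(cache$bwd, flip_tokens(dout), params, cfg)
  grads <- mapply(`+`, g1$grads, g2$grads, SIMPLIFY = FALSE)
  list(grads = grads, dx = g1$dx + flip_tokens(g2$dx))
}

# ---- stacked backbone --------------------------------------------------------

init_backbone_params <- function(cfg) {
  lapply(seq_len(cfg$depth), function(l) {
    c(list(ln_g = rep(1, cfg$embed_dim), ln_b = numeric(cfg$embed_dim)),
      init_mamba_params(cfg))
  })
}

#' Backbone forward pass
#'
#' For each layer: serialize per the layout schedule, pre-layer-norm, run the
#' (bidirectional) Mamba block, fold back, and (optionally) add the residual.
#'
#' @param h0 B x C x N x D latent tensor.
#' @param params list of per-layer parameter lists.
#' @param cfg model configuration (`depth`, `schedule`, `bidirectional`,
#'   `residual`).
#' @param keep_cache keep intermediates for backprop.
#' @return list(out = B x C x N x D, cache).
#' @export
backbone_fw <- function(h0, params, cfg, keep_cache = TRUE) {
  if (length(cfg$schedule) != cfg$depth)
    stop_domain("schedule length (%d) != depth (%d)", length(cfg$schedule), cfg$depth)
  h <- h0
  caches <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    v <- unfold_view(h, cfg$schedule[l])
    d <- dim(v$tokens)
    ln <- layernorm_fw(matrix(v$tokens, d[1L] * d[2L], d[3L]),
                       params[[l]]$ln_g, params[[l]]$ln_b)
    normed <- array(ln$out, d)
    blk <- if (cfg$bidirectional) {
      bidirectional_fw(normed, params[[l]], cfg, keep_cache)
    } else {
      mamba_block_fw(normed, params[[l]], cfg, keep_cache)
    }
    v$tokens <- blk$out
    upd <- fold_view(v)
    h_next <- if (cfg$residual) h + upd else upd
    caches[[l]] <- if (keep_cache) list(ln = ln, blk = blk$cache, dims = d,
                                        layout = cfg$schedule[l])
    h <- h_next
  }
  list(out = h, cache = caches)
}

backbone_bw <- function(cache, dout, params, cfg) {
  dh <- dout
  grads <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    cl <- cache[[l]]
    d <- cl$dims
    # gradient into this layer's folded update
    dupd_view <- unfold_view(dh, cl$layout)     # same permutation as forward fold
    dblk_out <- dupd_view$tokens
    bb <- if (cfg$bidirectional) {
      bidirectional_bw(cl$blk, dblk_out, params[[l]], cfg)
    } else {
      mamba_block_bw(cl$blk, dblk_out, params[[l]], cfg)
    }
    lb <- layernorm_bw(cl$ln$cache, matrix(bb$dx, d[1L] * d[2L], d[3L]))
    grads[[l]] <- c(list(ln_g = lb$dg, ln_b = lb$db), bb$grads)
    dv <- structure(list(tokens = array(lb$dx, d), layout = cl$layout,
                         c_dim = dim(dh)[2L], n_dim = dim(dh)[3L]),
                    class = "sequence_view")
    dh_layer <- fold_view(dv)
    dh <- if (cfg$residual) dh + dh_layer else dh_layer
  }
  list(grads = grads, dh = dh)
}
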