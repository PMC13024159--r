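# Dual-domain patch embedding: a temporal depthwise-separable convolution
# stream and a log-magnitude spectral stream, fused additively with a
# learnable positional table.
#
# Input is a B x C x N x P patch tensor; both streams map every (channel,
# patch) cell to a D-vector, so the latent tensor is B x C x N x D. The
# temporal stream sees the waveform (phase-sensitive); the spectral stream
# sees log(1 + |rFFT|) magnitudes (phase-invariant), anchoring the latent
# space in band power, which is far more stationary than raw phase.

n_freq_bins <- function(P) P %/% 2L + 1L

init_embedding_params <- function(cfg) {
  D <- cfg$embed_dim; k <- cfg$conv_kernel; F <- n_freq_bins(cfg$patch_size)
  p <- list()
  if (cfg$use_temporal) {
    p$conv_dw_w <- stats::rnorm(k, 0, 1 / sqrt(k))
    p$conv_dw_b <- 0
    p$conv_pw_w <- stats::rnorm(D, 0, 1)
    p$conv_pw_b <- numeric(D)
    p$gn_gamma <- rep(1, D)
    p$gn_beta <- numeric(D)
  }
  if (cfg$use_spectral) {
    p$w_freq <- matrix(stats::rnorm(F * D, 0, 1 / sqrt(F)), F, D)
  }
  if (cfg$use_linear_embed) {
    p$w_patch <- matrix(stats::rnorm(cfg$patch_size * D, 0, 1 / sqrt(cfg$patch_size)),
                        cfg$patch_size, D)
    p$b_patch <- numeric(D)
  }
  p$pos <- array(stats::rnorm(cfg$n_channels * cfg$n_patches * D, 0, cfg$pos_init_std),
                 c(cfg$n_channels, cfg$n_patches, D))
  p
}

#' Temporal embedding stream
#'
#' Depthwise temporal convolution (k taps, same padding) followed by a
#' pointwise projection to D feature maps, group normalization over the
#' feature maps, GELU, and mean pooling over the patch axis.
#'
#' @param x B x C x N x P array of patches.
#' @param params embedding parameter list.
#' @param cfg model configuration.
#' @return list with `out` (B x C x N x D) and `cache` for the backward pass.
#' @export
temporal_stream <- function(x, params, cfg) {
  d <- dim(x)
  if (length(d) != 4L) stop_domain("input must be B x C x N x P")
  P <- d[4L]
  if (P < cfg$conv_kernel)
    stop_domain("patch size %d shorter than conv kernel %d", P, cfg$conv_kernel)
  M <- d[1L] * d[2L] * d[3L]
  xm <- matrix(x, M, P)
  cv <- conv1d_same_fw(xm, params$conv_dw_w, params$conv_dw_b)
  # pointwise 1 -> D: z[m, p, d] = y[m, p] * w_d + b_d
  D <- cfg$embed_dim
  z <- array(cv$out, c(M, P, D)) *
    array(rep(params$conv_pw_w, each = M * P), c(M, P, D)) +
    array(rep(params$conv_pw_b, each = M * P), c(M, P, D))
  gn <- groupnorm_fw(z, params$gn_gamma, params$gn_beta, cfg$gn_groups)
  ac <- gelu_fw(gn$out)
  pooled <- colMeans(aperm(ac$out, c(2L, 1L, 3L)), dims = 1L)  # M x D
  list(out = array(pooled, c(d[1L], d[2L], d[3L], D)),
       cache = list(cv = cv, z_in = cv$out, gn = gn, ac = ac, dims = d, M = M,
                    P = P, D = D))
}

temporal_stream_bw <- function(cache, dout, params) {
  M <- cache$M; P <- cache$P; D <- cache$D
  dpool <- matrix(dout, M, D)
  dac <- aperm(array(rep(dpool / P, each = P), c(P, M, D)), c(2L, 1L, 3L))
  dgn_out <- gelu_bw(cache$ac$cache, dac)
  gb <- groupnorm_bw(cache$gn$cache, dgn_out)
  dz <- gb$dz
  wrep <- array(rep(params$conv_pw_w, each = M * P), c(M, P, D))
  yrep <- array(cache$z_in, c(M, P, D))
  d_pw_w <- colSums(matrix(dz * yrep, M * P, D))
  d_pw_b <- colSums(matrix(dz, M * P, D))
  dy <- matrix(rowSums(matrix(dz * wrep, M * P, D)), M, P)
  cb <- conv1d_same_bw(cache$cv$cache, dy)
  list(conv_dw_w = cb$dw, conv_dw_b = cb$db, conv_pw_w = d_pw_w,
       conv_pw_b = d_pw_b, gn_gamma = gb$dgamma, gn_beta = gb$dbeta)
}

#' Log-magnitude spectral features of a patch tensor
#'
#' Per patch: real-input FFT over the P samples, then log(1 + |.|) of the
#' P/2 + 1 magnitudes. Phase-invariant by construction.
#'
#' @param x B x C x N x P array.
#' @return M x (P/2+1) matrix of log-magnitudes, M = B*C*N (row-major over the
#'   flattened (b, c, n) index in column-major array order).
#' @export
log_magnitude_features <- function(x) {
  d <- dim(x)
  M <- prod(d[-4L]); P <- d[4L]
  xm <- matrix(x, M, P)
  F <- n_freq_bins(P)
  sp <- stats::mvfft(t(xm))[seq_len(F), , drop = FALSE]
  log1p(t(Mod(sp)))
}

#' Spectral embedding stream
#'
#' Projects the log-magnitude spectrum of each patch to D dimensions with a
#' bias-free linear map.
#'
#' @inheritParams temporal_stream
#' @return list with `out` (B x C x N x D) and `cache`.
#' @export
spectral_stream <- function(x, params, cfg) {
  d <- dim(x)
  if (length(d) != 4L) stop_domain("input must be B x C x N x P")
  lm <- log_magnitude_features(x)
  out <- lm %*% params$w_freq
  list(out = array(out, c(d[1L], d[2L], d[3L], cfg$embed_dim)),
       cache = list(lm = lm, dims = d))
}

spectral_stream_bw <- function(cache, dout) {
  D <- dim(dout)[4L]
  list(w_freq = crossprod(cache$lm, matrix(dout, nrow(cache$lm), D)))
}

#' Fuse embedding streams with the positional table
#'
#' Element-wise sum of the temporal and spectral latents plus a learnable
#' C x N x D positional encoding broadcast over the batch; no stream weighting
#' beyond the learnable parameters inside each stream.
#'
#' @param etime,efreq B x C x N x D arrays (either may be NULL when the
#'   corresponding stream is ablated).
#' @param pos C x N x D positional table.
#' @return B x C x N x D array.
#' @export
fuse_embedding <- function(etime, efreq, pos) {
  base <- etime %||% efreq
  if (is.null(base)) stop_domain("at least one stream required")
  d <- dim(base)
  if (!is.null(etime) && !is.null(efreq)) {
    if (!identical(dim(etime), dim(efreq))) stop_domain("stream shape mismatch")
    base <- etime + efreq
  }
  if (!identical(dim(pos), d[-1L])) stop_domain("positional table shape mismatch")
  base + aperm(array(pos, c(d[-1L], d[1L])), c(4L, 1L, 2L, 3L))
}

embedding_fw <- function(x, params, cfg) {
  caches <- list()
  etime <- efreq <- NULL
  if (cfg$use_linear_embed) {
    d <- dim(x)
    xm <- matrix(x, prod(d[-4L]), d[4L])
    lin <- linear_fw(xm, params$w_patch, params$b_patch)
    etime <- array(lin$out, c(d[-4L], cfg$embed_dim))
    caches$lin <- lin
  } else {
    if (cfg$use_temporal) {
      ts <- temporal_stream(x, params, cfg)
      etime <- ts$out; caches$ts <- ts
    }
    if (cfg$use_spectral) {
      ss <- spectral_stream(x, params, cfg)
      efreq <- ss$out; caches$ss <- ss
    }
  }
  out <- fuse_embedding(etime, efreq, params$pos)
  list(out = out, cache = caches)
}

embedding_bw <- function(cache, dout, params, cfg) {
  g <- list()
  d <- dim(dout)
  g$pos <- colSums(dout, dims = 1L)          # sum over batch -> C x N x D
  if (cfg$use_linear_embed) {
    lb <- linear_bw(cache$lin$cache, matrix(dout, prod(d[-4L]), d[4L]))
    g$w_patch <- lb$dW; g$b_patch <- lb$db
  } else {
    if (cfg$use_temporal)
      g <- c(g, temporal_stream_bw(cache$ts$cache, dout, params))
    if (cfg$use_spectral)
      g <- c(g, spectral_stream_bw(cache$ss$cache, dout))
  }
  g
}
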