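# Model configuration, parameter initialization, and the end-to-end forward /
# backward passes that chain embedding -> backbone -> attention -> MLP head.

#' Model configuration
#'
#' All architecture hyperparameters in one place. Defaults target desk-scale
#' CPU experiments; the dataset presets (see [model_preset()]) override the
#' input geometry.
#'
#' @param n_channels EEG channels C.
#' @param n_classes classes K (>= 2).
#' @param patch_size samples per patch P.
#' @param n_patches patches per trial N.
#' @param embed_dim latent width D.
#' @param conv_kernel temporal-stream depthwise kernel length (odd).
#' @param gn_groups group-norm groups (must divide `embed_dim`).
#' @param pos_init_std std of the positional table initialization.
#' @param d_state SSD state size S.
#' @param head_dim SSD head dimension; `expand*embed_dim` must be divisible.
#' @param expand width expansion factor inside the Mamba block.
#' @param conv_kernel_seq short causal conv kernel inside the block.
#' @param dt_min,dt_max clamp bounds for the softplus-discretized step size.
#' @param a_init range (lo, hi) for the per-head decay magnitude; A is
#'   initialized in -(hi, lo), strictly negative for stability.
#' @param depth number of backbone layers.
#' @param schedule per-layer serialization layouts; default alternates
#'   spatial-first then temporal-first.
#' @param bidirectional run every block forward and flipped with shared weights.
#' @param residual pre-norm residual wrapping around each backbone layer.
#' @param n_attn_heads heads of the global attention layer.
#' @param mlp_hidden hidden widths of the MLP classifier.
#' @param mlp_dropout dropout probabilities per hidden MLP layer.
#' @param smoothing label-smoothing epsilon.
#' @param variant ablation variant; see [model_variant()].
#' @return a `model_config` list.
#' @export
model_config <- function(n_channels, n_classes, patch_size = 200L,
                         n_patches = 4L, embed_dim = 32L, conv_kernel = 7L,
                         gn_groups = 4L, pos_init_std = 0.02, d_state = 16L,
                         head_dim = 16L, expand = 2L, conv_kernel_seq = 4L,
                         dt_min = 0.001, dt_max = 0.1, a_init = c(1, 8),
                         depth = 4L, schedule = NULL, bidirectional = TRUE,
                         residual = TRUE, n_attn_heads = 4L,
                         mlp_hidden = c(256L, 64L), mlp_dropout = c(0.5, 0.3),
                         smoothing = 0.1, variant = "full") {
  n_channels <- check_count(n_channels, "n_channels", 1L)
  n_classes <- check_count(n_classes, "n_classes", 2L)
  patch_size <- check_count(patch_size, "patch_size", 2L)
  n_patches <- check_count(n_patches, "n_patches", 1L)
  embed_dim <- check_count(embed_dim, "embed_dim", 1L)
  depth <- check_count(depth, "depth", 0L)
  if (conv_kernel %% 2L == 0L) stop_domain("conv_kernel must be odd")
  if (embed_dim %% gn_groups != 0L) stop_domain("gn_groups must divide embed_dim")
  if (embed_dim %% n_attn_heads != 0L)
    stop_domain("n_attn_heads must divide embed_dim")
  E <- expand * embed_dim
  if (E %% head_dim != 0L) stop_domain("head_dim must divide expand*embed_dim")
  if (dt_min >= dt_max) stop_domain("dt_min must be < dt_max")
  if (is.null(schedule))
    schedule <- rep(c("spatial_first", "temporal_first"), length.out = depth)
  if (!all(schedule %in% LAYOUTS)) stop_domain("unknown layout in schedule")
  if (length(schedule) != depth) stop_domain("schedule length != depth")
  cfg <- list(n_channels = n_channels, n_classes = n_classes,
              patch_size = patch_size, n_patches = n_patches,
              embed_dim = embed_dim, conv_kernel = as.integer(conv_kernel),
              gn_groups = as.integer(gn_groups), pos_init_std = pos_init_std,
              d_state = as.integer(d_state), head_dim = as.integer(head_dim),
              expand = as.integer(expand), n_ssd_heads = as.integer(E %/% head_dim),
              conv_kernel_seq = as.integer(conv_kernel_seq),
              dt_min = dt_min, dt_max = dt_max, a_init = a_init,
              depth = depth, schedule = schedule,
              bidirectional = isTRUE(bidirectional), residual = isTRUE(residual),
              n_attn_heads = as.integer(n_attn_heads),
              mlp_hidden = as.integer(mlp_hidden), mlp_dropout = mlp_dropout,
              smoothing = smoothing,
              use_temporal = TRUE, use_spectral = TRUE, use_linear_embed = FALSE,
              use_backbone = depth > 0L, use_attention = TRUE,
              variant = "full")
  class(cfg) <- "model_config"
  if (!identical(variant, "full")) cfg <- model_variant(cfg, variant)
  cfg
}

ABLATION_VARIANTS <- c("full", "no_temporal_stream", "no_spectral_stream",
                       "no_dual_domain", "no_backbone", "pure_mamba2")

#' Derive an ablation variant of a configuration
#'
#' `no_temporal_stream` drops the convolutional stream; `no_spectral_stream`
#' drops the FFT stream; `no_dual_domain` replaces both with a plain linear
#' patch projection; `no_backbone` removes the state-space stack (embedding ->
#' attention -> head); `pure_mamba2` removes the global attention layer
#' (embedding -> backbone -> head).
#'
#' @param cfg a `model_config`.
#' @param variant one of `r paste(ABLATION_VARIANTS, collapse = ", ")`.
#' @return modified `model_config`.
#' @export
model_variant <- function(cfg, variant) {
  variant <- match.arg(variant, ABLATION_VARIANTS)
  cfg$variant <- variant
  switch(variant,
    full = cfg,
    no_temporal_stream = { cfg$use_temporal <- FALSE; cfg },
    no_spectral_stream = { cfg$use_spectral <- FALSE; cfg },
    no_dual_domain = {
      cfg$use_temporal <- FALSE; cfg$use_spectral <- FALSE
      cfg$use_linear_embed <- TRUE; cfg
    },
    no_backbone = { cfg$use_backbone <- FALSE; cfg },
    pure_mamba2 = { cfg$use_attention <- FALSE; cfg }
  )
}

#' Dataset-style configuration presets
#'
#' `"faced"`: 32-channel, 9-class montage, no band-pass (matching the
#' preprocessing protocol for that corpus); `"seedv"`: 62-channel, 5-class
#' montage with the 0.3-75 Hz band-pass enabled.
#'
#' @param name `"faced"` or `"seedv"`.
#' @param n_patches patches per trial (free parameter; depends on epoching).
#' @param ... further overrides passed to [model_config()].
#' @return list with `model` (a `model_config`) and `preprocess`
#'   (a [preprocess_config()]).
#' @export
model_preset <- function(name = c("faced", "seedv"), n_patches = 4L, ...) {
  name <- match.arg(name)
  if (name == "faced") {
    list(model = model_config(n_channels = 32L, n_classes = 9L,
                              n_patches = n_patches, ...),
         preprocess = preprocess_config(target_sfreq = 200, band = c(0.3, 75),
                                        apply_bandpass = FALSE, patch_size = 200L))
  } else {
    list(model = model_config(n_channels = 62L, n_classes = 5L,
                              n_patches = n_patches, ...),
         preprocess = preprocess_config(target_sfreq = 200, band = c(0.3, 75),
                                        apply_bandpass = TRUE, patch_size = 200L))
  }
}

#' Initialize a model
#'
#' @param cfg a `model_config`.
#' @param seed integer seed for weight initialization.
#' @return an `eeg_model`: list(cfg, params).
#' @export
model_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  params <- withr::with_seed(as.integer(seed), {
    p <- list(embed = init_embedding_params(cfg))
    if (cfg$use_backbone) p$backbone <- init_backbone_params(cfg)
    p$head <- init_head_params(cfg)
    p
  })
  structure(list(cfg = cfg, params = params), class = "eeg_model")
}

#' @export
print.eeg_model <- function(x, ...) {
  cat(sprintf(paste0("<eeg_model> variant=%s C=%d N=%d P=%d D=%d depth=%d ",
                     "K=%d (%d parameters)\n"),
              x$cfg$variant, x$cfg$n_channels, x$cfg$n_patches,
              x$cfg$patch_size, x$cfg$embed_dim, x$cfg$depth, x$cfg$n_classes,
              n_params(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model an `eeg_model`.
#' @return integer count.
#' @export
n_params <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

# flatten the nested parameter list into a flat named list of arrays
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v)) out <- c(out, flatten_params(v, paste0(key, ".")))
    else out[[key]] <- v
  }
  out
}

# write a flat named list of arrays back into the nested structure
unflatten_params <- function(flat, skeleton) {
  walk <- function(p, prefix) {
    for (nm in names(p)) {
      key <- paste0(prefix, nm)
      if (is.list(p[[nm]])) p[[nm]] <- walk(p[[nm]], paste0(key, "."))
      else p[[nm]] <- flat[[key]]
    }
    p
  }
  walk(skeleton, "")
}

#' Full model forward pass
#'
#' @param model an `eeg_model`.
#' @param x B x C x N x P array of patched trials.
#' @param training enables dropout.
#' @param keep_cache keep intermediates for [model_backward()].
#' @return list(logits = B x K, cache).
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = training) {
  cfg <- model$cfg; p <- model$params
  d <- dim(x)
  if (length(d) != 4L || d[2L] != cfg$n_channels || d[3L] != cfg$n_patches ||
      d[4L] != cfg$patch_size)
    stop_domain("input must be B x %d x %d x %d (got %s)", cfg$n_channels,
                cfg$n_patches, cfg$patch_size, paste(d, collapse = " x "))
  emb <- embedding_fw(x, p$embed, cfg)
  h <- emb$out
  bb <- NULL
  if (cfg$use_backbone && cfg$depth > 0L) {
    bb <- backbone_fw(h, p$backbone, cfg, keep_cache)
    h <- bb$out
  }
  at <- NULL
  if (cfg$use_attention) {
    at <- global_recalibrate(h, p$head, cfg, keep_cache)
    h <- at$out
  }
  mh <- mlp_head_fw(h, p$head, cfg, training, keep_cache)
  list(logits = mh$out,
       cache = if (keep_cache) list(emb = emb$cache, bb = bb$cache,
                                    at = at$cache, mh = mh$cache))
}

#' Full model backward pass
#'
#' @param model an `eeg_model`.
#' @param cache cache from [model_forward()] with `keep_cache = TRUE`.
#' @param dlogits gradient of the loss w.r.t. the logits.
#' @return nested gradient list matching `model$params`.
#' @export
model_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg; p <- model$params
  g <- list()
  mb <- mlp_head_bw(cache$mh, dlogits)
  g$head <- list(mlp = mb$grads)
  dh <- mb$dh
  if (cfg$use_attention) {
    ab <- global_recalibrate_bw(cache$at, dh, cfg)
    g$head <- c(g$head, ab$grads)
    dh <- ab$dh
  }
  if (cfg$use_backbone && cfg$depth > 0L) {
    bb <- backbone_bw(cache$bb, dh, p$backbone, cfg)
    g$backbone <- bb$grads
    dh <- bb$dh
  }
  g$embed <- embedding_bw(cache$emb, dh, p$embed, cfg)
  g
}

#' Predict class probabilities for a batch of patched trials
#'
#' @param object an `eeg_model`.
#' @param x B x C x N x P array.
#' @param ... unused.
#' @return a prediction list (see [as_prediction()]).
#' @export
predict.eeg_model <- function(object, x, ...) {
  as_prediction(model_forward(object, x, training = FALSE,
                              keep_cache = FALSE)$logits)
}
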