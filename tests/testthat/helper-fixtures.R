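# Shared small fixtures, built in code at test time.

# a deliberately tiny model geometry that exercises every component
tiny_cfg <- function(...) {
  defaults <- list(n_channels = 3L, n_classes = 2L, patch_size = 16L,
                   n_patches = 2L, embed_dim = 8L, conv_kernel = 5L,
                   gn_groups = 2L, d_state = 4L, head_dim = 8L, expand = 2L,
                   depth = 2L, n_attn_heads = 2L, mlp_hidden = c(10L, 6L),
                   mlp_dropout = c(0, 0))
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_batch <- function(cfg, B = 4L, seed = 11L) {
  withr::with_seed(seed, array(
    rnorm(B * cfg$n_channels * cfg$n_patches * cfg$patch_size),
    c(B, cfg$n_channels, cfg$n_patches, cfg$patch_size)))
}

# the 2-class band-power task used by the learnability and ablation checks:
# class 0 carries alpha (8-13 Hz) power, class 1 low-gamma (25-35 Hz), both
# as randomized-phase band-limited noise at the given effect size
bandpower_task_spec <- function(effect = 4, n_channels = 4L, seed = 5L) {
  synthetic_task_spec(n_channels = n_channels, n_classes = 2L, sfreq = 128,
                      duration = 2, noise_exponent = 1,
                      class_bands = list(c(8, 13), c(25, 35)),
                      effect_size = effect, seed = seed)
}

bandpower_model_cfg <- function(n_channels = 4L, ...) {
  defaults <- list(n_channels = n_channels, n_classes = 2L, patch_size = 64L,
                   n_patches = 4L, embed_dim = 16L, conv_kernel = 7L,
                   gn_groups = 4L, d_state = 8L, head_dim = 8L, expand = 2L,
                   depth = 2L, n_attn_heads = 2L, mlp_hidden = c(32L, 16L),
                   mlp_dropout = c(0.3, 0.2), smoothing = 0.1)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

random_mamba_params <- function(cfg, seed = 21L) {
  withr::with_seed(seed, eegmamba:::init_mamba_params(cfg))
}
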