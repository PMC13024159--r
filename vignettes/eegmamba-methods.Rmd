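---
title: "Hybrid state-space / attention decoding of multichannel EEG: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid state-space / attention decoding of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmamba)
```

## The problem

Decoding affective or cognitive state from scalp EEG means classifying a
C-channel voltage matrix X in R^{C x T} (microvolts, hundreds of Hz) into one
of K classes. Two structural properties make this hard: the signal is
non-stationary, and its information is entangled across two orthogonal axes —
*spatial* (instantaneous co-activation of electrodes, i.e. functional
connectivity) and *temporal* (the evolution of the neural state across the
trial). `eegmamba` implements a classifier built around three ideas:

1. **Dual-domain patch embedding.** The trial is cut into N non-overlapping
   patches of P samples. Each (channel, patch) cell is embedded twice: a
   *temporal* stream (depthwise temporal convolution, pointwise projection to
   D maps, group normalization, GELU, mean pooling) that sees waveform shape,
   and a *spectral* stream that projects log(1 + |rFFT|) magnitudes through a
   bias-free linear map. Because EEG power follows roughly 1/f, raw FFT
   magnitudes would be dominated by low frequencies; the log(1+x) compression
   keeps gamma-range detail alive next to delta-range power. The two streams
   are summed with a learnable C x N x D positional table — no fixed mixing
   weights; each stream's own parameters set its contribution.

2. **Decoupled spatial-temporal scanning.** The backbone is a stack of
   selective state-space (Mamba2/SSD-style) blocks. A 1-D scan over the
   C x N token grid must pick a serialization, and any fixed choice damages
   either spatial adjacency or temporal continuity. Here the serialization is
   reconfigured per layer: *spatial-first* layers put the channel index in
   the inner loop (the scan sweeps the whole montage at one time step before
   advancing), *temporal-first* layers put the patch index in the inner loop
   (the scan follows one channel's full time course before the next channel).
   The default schedule strictly alternates, starting spatial-first. Scans
   are causal, so every block is applied bidirectionally,
   `out = block(v) + flip(block(flip(v)))`, with shared weights.

3. **Global attention recalibration.** A recurrent state compresses history;
   over long token sequences it can forget salient early events. A single
   pre-norm multi-head self-attention layer over all C*N tokens, with a
   residual connection, lets the classifier compare any two channel-time
   positions directly before the MLP head.

Training minimizes label-smoothing cross-entropy,
`loss = -sum_i [(1-eps) y_i + eps/K] log p_i`, with AdamW.

## The selective scan

Each head carries a state S in R^{S x E} updated per token:

    S_t = exp(dt_t * A) S_{t-1} + dt_t * B_t x_t^T
    y_t = S_t^T C_t + D_skip . x_t

`A < 0` is a per-head scalar decay (Mamba2 convention; keeps `|exp(dt A)| < 1`,
hence unconditional stability); `dt_t`, `B_t`, `C_t` are linear functions of
the post-convolution input (the *selectivity* — the model chooses per token
how much to write and read). `dt` passes through a softplus and is clamped to
`[dt_min, dt_max] = [0.001, 0.1]`; the decay uses zero-order-hold
discretization `exp(dt A)` while the input uses the Euler form `dt * B`, the
standard mixed scheme. The plain sequential recurrence is the normative
implementation; the test suite holds it to a dense O(L^2) lower-triangular
operator oracle at 1e-6, checks strict causality by token perturbation, and
verifies the batched multi-head version and all hand-derived gradients
against finite differences.

No deep-learning framework is available in the target environment, so every
forward and backward pass (convolutions, group/layer norm, the scan,
attention, the MLP) is written in base R. That choice is also a feature: the
scan recurrence above *is* the contribution under test, and owning its
gradient makes the oracle checks meaningful.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `patch_size` P | 200 samples | 1 s at the 200 Hz working rate; patches act as the discretization step of the latent ODE |
| `embed_dim` D | 32 | latent width; divisible by `gn_groups` = 4 and `n_attn_heads` = 4 |
| `conv_kernel` | 7 (odd) | temporal receptive field of ~35 ms at 200 Hz |
| `d_state` S | 16 | SSD state size per head |
| `expand` | 2 | block inner width E = 2D |
| `head_dim` | 16 | E/head_dim heads per block |
| `dt_min`, `dt_max` | 0.001, 0.1 | step-size clamp; bounds the decay spectrum |
| `a_init` | (1, 8) | A initialized in -(1, 8), log-uniform |
| `depth` | 4 | alternating spatial/temporal schedule |
| `mlp_hidden` | 256, 64 | three-layer head with ELU |
| `mlp_dropout` | 0.5, 0.3 | regularization for small EEG corpora |
| `smoothing` eps | 0.1 | label smoothing; a conventional value, exposed in config |
| optimizer | AdamW, lr 1e-4, wd 1e-4, batch 32 | standard recipe for this model family at corpus scale; desk-scale runs in this package use larger lr (1e-3..3e-3) and smaller geometry, a deliberate rescaling for CPU budgets |

Preprocessing: polyphase resampling to 200 Hz; an optional zero-phase
4th-order Butterworth band-pass at 0.3-75 Hz that the 62-channel 5-class
preset enables and the 32-channel 9-class preset disables (matching the
respective corpus protocols); trailing samples beyond N*P are truncated, not
zero-padded, to avoid injecting spectral transients. Subject-level splits
take subjects in order of first appearance (e.g. 80 train / 20 validation /
remaining 23 test on a 123-subject roster); an alternative per-subject trial
split (first 5 / next 5 / last 5) covers 15-trial-per-subject corpora.

## What the synthetic generator emulates — and what it does not

`synthetic_task_spec()` defines trials as `mixing %*% (background + class
oscillation)` per channel: the background is synthesized in the frequency
domain with amplitude proportional to f^(-alpha/2) and uniform random phases
(exact spectral control; alpha defaults to 1, typical of resting EEG;
background RMS fixed at 10 uV), and the class signal is band-limited Gaussian
noise — random amplitude *and* phase per trial — whose in-band power is
exactly `effect_size` times the background's in-band power. Band-limited
noise rather than a sinusoid is deliberate: with a fixed sinusoid a single
FFT bin would solve the task, trivializing the spectral stream. One RNG
stream per trial is derived from (seed, trial index), so trial i is
independent of dataset size.

The generator does **not** model volume-conduction forward physics, ocular or
myogenic artifacts, electrode drift, or inter-subject covariate shift. A
green learnability test therefore establishes that the architecture and its
gradients can extract class-conditional band-power structure from 1/f noise
at realistic SNR — not that it reaches any particular accuracy on real,
artifact-laden, subject-shifted EEG. Benchmark-level accuracy on the
restricted-access 9-class (32-channel) and 5-class (62-channel) emotion
corpora would require the corpora themselves and GPU-scale training, both out
of scope here; consequently the artifact defines no numeric acceptance
targets, and `scripts/acceptance.R` reports an empty target set.

## Numerical choices and degenerate inputs

- Zero-phase filtering runs each Butterworth biquad forward and backward with
  odd-reflection padding and steady-state initial conditions, so a constant
  input yields (numerically) zero high-pass output rather than a slow
  transient; the effective magnitude response is the squared Butterworth,
  which the tests compare to the prewarped analog response.
- The resampler is windowed-sinc polyphase with gain-normalized taps; output
  length is exactly `round(T * target/source)`.
- `log1p` keeps the spectral stream exact at zero input (zero in, zero out,
  since W_freq carries no bias) — a testable invariant.
- Group normalization runs over D feature maps within each (channel, patch)
  location, `gn_groups = 4`; normalizing across channels instead would be
  defensible, and per-location normalization is the choice that keeps
  channels exchangeable.
- The DC bin is included in the spectral projection (P/2 + 1 bins).
- dt clamping passes no gradient outside the clamp band (hard clamp).
- Ties in argmax resolve to the lowest class index, deterministically.
- `A` is parameterized as `-exp(A_log)`, so optimization can never cross into
  instability.

## Open design points, resolved

- *How many spatial-first layers should precede the switch* has no single
  right answer; the schedule is a user-facing config with a strictly
  alternating default starting spatial-first.
- *Whether bidirectionality applies to every layer* is unstated; applied to
  all layers here (flag `bidirectional` restores the literal causal reading).
- *Residual connections inside the backbone* are an extension (the source
  shows a residual only at the attention layer); they are on by default for
  trainability and exposed as `residual` so the literal reading is runnable.
- The head's documented input width (P rather than D after the embedding) is
  treated as a typo; the flattened feature is C*N*D.
- MLP widths, dropout rates, and eps are declared package choices (the
  defaults above), all exposed in `model_config()`.
- The "without backbone" ablation is ambiguous between removing the
  state-space stack and removing the attention layer; both are provided
  (`no_backbone`, `pure_mamba2`).
- EDF input was dropped: no EDF reader exists in the supported dependency
  set. The archive fixture format (`write_fixture`/`read_fixture`) is the
  supported interchange route and round-trips float64 exactly.

## Known limitations

Pure-R training is CPU-bound and suits desk-scale experiments (thousands of
parameters, tens of epochs, minutes); it is not a route to the
million-parameter, 200-epoch GPU configuration. Dropout inside attention
weights is omitted (only the MLP uses dropout). The chunked/parallel scan
path is not implemented — only the reference sequential scan — so long-L
throughput is linear but with an R-loop constant.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_task_spec(n_channels = 4, n_classes = 2, sfreq = 128,
                            duration = 2, class_bands = list(c(8, 13), c(25, 35)),
                            effect_size = 4, seed = 5)
ds <- make_dataset(spec, n_trials_per_class = 100, n_subjects = 10)
tens <- dataset_tensors(ds, preprocess_config(target_sfreq = 128, band = NULL,
                                              patch_size = 64))
sp <- split_subjects(tens$subject_ids, n_train = 6, n_val = 2)
cfg <- model_config(n_channels = 4, n_classes = 2, patch_size = 64,
                    n_patches = 4, embed_dim = 16, d_state = 8, head_dim = 8,
                    depth = 2, n_attn_heads = 2, mlp_hidden = c(32, 16),
                    mlp_dropout = c(0.3, 0.2))
model <- model_init(cfg, seed = 7)
fit <- train_model(model, eegmamba:::subset_tensors(tens, sp$train),
                   eegmamba:::subset_tensors(tens, sp$val),
                   train_config(lr = 3e-3, epochs = 30, batch_size = 32, seed = 7))
fit$best_val_balacc
```

Every empirical number quoted in the package documentation is computed by the
test suite or the scripts in this repository; none are transcribed from
external sources.
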