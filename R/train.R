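# AdamW training loop with seeded shuffling, per-epoch history, and model
# selection by validation balanced accuracy.

#' Training configuration
#'
#' Defaults are the standard recipe for EEG decoders of this family (AdamW,
#' lr 1e-4, weight decay 1e-4, batch size 32); `epochs` defaults to a
#' desk-scale 30 (full-scale GPU runs typically use 200).
#'
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed master seed driving shuffling and dropout.
#' @param early_stop_balacc optional validation balanced-accuracy (in %) at
#'   which training halts early.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, batch_size = 32L,
                         epochs = 30L, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L, early_stop_balacc = NULL,
                         verbose = FALSE) {
  if (lr < 0) stop_domain("lr must be >= 0")
  batch_size <- check_count(batch_size, "batch_size", 1L)
  epochs <- check_count(epochs, "epochs", 1L)
  structure(list(lr = lr, weight_decay = weight_decay, batch_size = batch_size,
                 epochs = epochs, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed),
                 early_stop_balacc = early_stop_balacc,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# one AdamW step on flat parameter/gradient lists; state carries m, v, t
adamw_step <- function(flat_p, flat_g, state, cfg) {
  if (is.null(state)) {
    state <- list(m = lapply(flat_p, function(x) x * 0),
                  v = lapply(flat_p, function(x) x * 0), t = 0L)
  }
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(flat_p)) {
    gnm <- flat_g[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gnm
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gnm^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat_p[[nm]] <- flat_p[[nm]] -
      cfg$lr * (mhat / (sqrt(vhat) + cfg$adam_eps) +
                  cfg$weight_decay * flat_p[[nm]])
  }
  list(params = flat_p, state = state)
}

#' Convert a labeled dataset to model-ready tensors
#'
#' Preprocesses every trial (resample, optional band-pass, patching) and
#' stacks the results into a B x C x N x P array.
#'
#' @param ds an `eeg_dataset`.
#' @param pre_cfg a [preprocess_config()].
#' @return list(x = B x C x N x P array, y = integer labels,
#'   subject_ids = integer vector).
#' @export
dataset_tensors <- function(ds, pre_cfg = preprocess_config()) {
  stopifnot(inherits(ds, "eeg_dataset"))
  n <- length(ds$trials)
  if (n == 0L) stop_domain("empty dataset")
  pts <- lapply(ds$trials, preprocess_trial, cfg = pre_cfg)
  d1 <- dim(pts[[1L]]$patches)
  x <- array(0, c(n, d1))
  for (i in seq_len(n)) x[i, , , ] <- pts[[i]]$patches
  list(x = x, y = as.integer(ds$labels), subject_ids = ds$subject_ids)
}

subset_tensors <- function(tensors, idx) {
  list(x = tensors$x[idx, , , , drop = FALSE], y = tensors$y[idx],
       subject_ids = tensors$subject_ids[idx])
}

evaluate_tensors <- function(model, tensors, batch_size = 64L) {
  n <- length(tensors$y)
  preds <- integer(n)
  loss <- 0
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    fw <- model_forward(model, tensors$x[idx, , , , drop = FALSE],
                        training = FALSE, keep_cache = FALSE)
    preds[idx] <- max.col(fw$logits, ties.method = "first") - 1L
    loss <- loss + label_smoothing_ce(fw$logits, tensors$y[idx],
                                      model$cfg$smoothing)$loss * length(idx)
  }
  list(metrics = compute_metrics(tensors$y, preds,
                                 n_classes = model$cfg$n_classes),
       loss = loss / n, preds = preds)
}

#' Train a model with AdamW
#'
#' Minimizes the label-smoothing cross-entropy with decoupled weight decay,
#' records per-epoch train/validation loss and metrics, and keeps the
#' checkpoint with the best validation balanced accuracy.
#'
#' @param model an `eeg_model` from [model_init()].
#' @param train_tensors,val_tensors lists from [dataset_tensors()] (optionally
#'   subset with the split helpers).
#' @param cfg a [train_config()].
#' @return list(model = best checkpoint, final_model, history = data.frame,
#'   best_epoch, best_val_balacc).
#' @export
train_model <- function(model, train_tensors, val_tensors, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  n <- length(train_tensors$y)
  if (n == 0L || length(val_tensors$y) == 0L) stop_domain("datasets must be non-empty")
  flat <- flatten_params(model$params)
  state <- NULL
  history <- list()
  best <- list(balacc = -Inf, flat = flat, epoch = 0L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- withr::with_seed(derive_seed(cfg$seed, epoch), sample.int(n))
    ep_loss <- 0
    step <- 0L
    for (s in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      xb <- train_tensors$x[idx, , , , drop = FALSE]
      yb <- train_tensors$y[idx]
      step <- step + 1L
      fw <- withr::with_seed(derive_seed(cfg$seed, epoch, step),
        model_forward(model, xb, training = TRUE, keep_cache = TRUE))
      ls <- label_smoothing_ce(fw$logits, yb, model$cfg$smoothing)
      if (!is.finite(ls$loss))
        stop_domain("non-finite loss at epoch %d step %d", epoch, step)
      ep_loss <- ep_loss + ls$loss * length(idx)
      grads <- model_backward(model, fw$cache, ls$dlogits)
      upd <- adamw_step(flat, flatten_params(grads), state, cfg)
      flat <- upd$params; state <- upd$state
      model$params <- unflatten_params(flat, model$params)
    }
    ev <- evaluate_tensors(model, val_tensors)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / n, val_loss = ev$loss,
      val_balacc = ev$metrics$balanced_accuracy,
      val_kappa = ev$metrics$cohens_kappa,
      val_wf1 = ev$metrics$weighted_f1)
    if (cfg$verbose)
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val balacc %.2f",
                      epoch, ep_loss / n, ev$loss, ev$metrics$balanced_accuracy))
    if (ev$metrics$balanced_accuracy > best$balacc) {
      best <- list(balacc = ev$metrics$balanced_accuracy, flat = flat,
                   epoch = epoch)
    }
    if (!is.null(cfg$early_stop_balacc) &&
        ev$metrics$balanced_accuracy >= cfg$early_stop_balacc) break
  }
  best_model <- model
  best_model$params <- unflatten_params(best$flat, model$params)
  list(model = best_model, final_model = model,
       history = do.call(rbind, history), best_epoch = best$epoch,
       best_val_balacc = best$balacc)
}
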