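# Evaluation metrics: balanced accuracy, Cohen's kappa, support-weighted F1
# (all reported in percent), plus the confusion matrix and result export.

#' Classification metrics for multiclass predictions
#'
#' Balanced accuracy = macro-averaged per-class recall x 100 (classes with no
#' true instances are excluded from the average); Cohen's kappa =
#' (p_o - p_e) / (1 - p_e) x 100 with p_e from the marginal products;
#' weighted F1 = support-weighted per-class F1 x 100.
#'
#' @param y_true,y_pred integer labels in 0..K-1, equal length.
#' @param n_classes K (inferred from the labels when omitted).
#' @return an `eeg_metrics` list: `balanced_accuracy`, `cohens_kappa`,
#'   `weighted_f1` (percent) and `confusion` (K x K counts, rows = truth).
#' @export
compute_metrics <- function(y_true, y_pred, n_classes = NULL) {
  n <- length(y_true)
  if (n == 0L) stop_domain("empty input")
  if (length(y_pred) != n) stop_domain("y_true and y_pred lengths differ")
  K <- n_classes %||% (max(y_true, y_pred) + 1L)
  if (any(y_true < 0 | y_true >= K | y_pred < 0 | y_pred >= K))
    stop_domain("labels must lie in [0, %d)", K)
  cm <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1L), pred = 0:(K - 1L)))
  for (i in seq_len(n)) cm[y_true[i] + 1L, y_pred[i] + 1L] <-
      cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  tp <- diag(cm)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  balacc <- mean(recall, na.rm = TRUE) * 100
  po <- sum(tp) / n
  pe <- sum(support * pred_n) / n^2
  kappa <- if (pe >= 1) 0 else (po - pe) / (1 - pe) * 100
  f1 <- ifelse(precision + recall > 0 & !is.na(recall),
               2 * precision * recall / (precision + recall), 0)
  wf1 <- sum(f1[support > 0] * support[support > 0]) / n * 100
  structure(list(balanced_accuracy = balacc, cohens_kappa = kappa,
                 weighted_f1 = wf1, confusion = cm, n = n),
            class = "eeg_metrics")
}

#' @export
print.eeg_metrics <- function(x, ...) {
  cat(sprintf("balanced accuracy %.2f%%  Cohen's kappa %.2f%%  weighted F1 %.2f%%  (n = %d)\n",
              x$balanced_accuracy, x$cohens_kappa, x$weighted_f1, x$n))
  invisible(x)
}

#' Export metrics to disk
#'
#' Writes `metrics.json` (the three percentage metrics, n, and provenance),
#' `confusion.csv` (K x K counts with labeled rows/columns), and
#' `confusion.pdf` (a rendered heat map).
#'
#' @param metrics an `eeg_metrics`.
#' @param dir output directory (created if needed).
#' @param class_names optional class labels for the figure/CSV.
#' @param seed optional seed to record in the JSON.
#' @return invisible character vector of the files written.
#' @export
export_results <- function(metrics, dir, class_names = NULL, seed = NULL) {
  stopifnot(inherits(metrics, "eeg_metrics"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- nrow(metrics$confusion)
  if (is.null(class_names)) class_names <- as.character(0:(K - 1L))
  jf <- file.path(dir, "metrics.json")
  jsonlite::write_json(list(schema_version = "1.0",
                            balanced_accuracy = metrics$balanced_accuracy,
                            cohens_kappa = metrics$cohens_kappa,
                            weighted_f1 = metrics$weighted_f1,
                            n = metrics$n, seed = seed),
                       jf, auto_unbox = TRUE, digits = NA, null = "null")
  cf <- file.path(dir, "confusion.csv")
  cm <- metrics$confusion
  dimnames(cm) <- list(class_names, class_names)
  utils::write.csv(as.data.frame(cm), cf)
  pf <- file.path(dir, "confusion.pdf")
  grDevices::pdf(pf, width = 5, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  prop <- metrics$confusion / pmax(rowSums(metrics$confusion), 1L)
  graphics::image(seq_len(K), seq_len(K), t(prop[K:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True",
                  main = "Confusion matrix (row-normalized)")
  graphics::axis(1L, at = seq_len(K), labels = class_names, las = 2)
  graphics::axis(2L, at = seq_len(K), labels = rev(class_names), las = 2)
  for (i in seq_len(K)) for (j in seq_len(K))
    graphics::text(j, K - i + 1L, sprintf("%.2f", prop[i, j]), cex = 0.7)
  invisible(c(jf, cf, pf))
}

#' Read back metrics written by [export_results()]
#'
#' @param dir directory containing `metrics.json`.
#' @return named list of the stored values.
#' @export
read_results <- function(dir) {
  jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
}

#' Train and evaluate one ablation variant
#'
#' Builds the requested variant with the same initialization seed and data,
#' trains it, and reports test metrics — the comparison harness behind
#' directional ablation checks (the full model should dominate variants that
#' remove the component a task depends on).
#'
#' @param variant one of the ablation variant names (see [model_variant()]).
#' @param task list with `train`, `val`, `test` tensor lists (from
#'   [dataset_tensors()] and a split) and `model_cfg` (a `model_config`).
#' @param cfg a [train_config()].
#' @return list(variant, metrics = test `eeg_metrics`, n_params, history).
#' @export
run_ablation <- function(variant, task, cfg = train_config()) {
  vcfg <- model_variant(task$model_cfg, variant)
  model <- model_init(vcfg, seed = cfg$seed)
  fit <- train_model(model, task$train, task$val, cfg)
  ev <- evaluate_tensors(fit$model, task$test)
  list(variant = variant, metrics = ev$metrics, n_params = n_params(model),
       history = fit$history, best_val_balacc = fit$best_val_balacc)
}
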