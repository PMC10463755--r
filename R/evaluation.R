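#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) score
#' pairs ranked correctly, ties counted half. Invariant under strictly
#' monotone score transforms.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return ROC-AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1L; neg <- labels == 0L
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L)
    stop_metric("ROC-AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision (step) formulation: scores are processed in
#' descending order with tied scores grouped; each group contributes its
#' recall increment times the precision at the end of the group. No
#' interpolation. A constant scorer gets the prevalence.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in (0, 1].
#' @export
pr_auc <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop_metric("PR-AUC undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  np <- grp_end
  dtp <- diff(c(0, tp))
  sum(dtp * tp / np) / n1
}

#' Recall and F1 at a probability threshold
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold in (0, 1); scores at or above
#'   it predict positive.
#' @return Named list `recall`, `f1` (both 0 when undefined).
#' @export
recall_f1 <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (prec + recall == 0) 0 else 2 * prec * recall / (prec + recall)
  list(recall = recall, f1 = f1)
}

#' Evaluate a model on labelled examples
#'
#' @param object A `dti_model` or `dti_fit`.
#' @param examples Labelled example data frame.
#' @param threshold Threshold for recall/F1.
#' @return A metrics record: list with `roc_auc`, `pr_auc`, `recall`,
#'   `f1`, `n`.
#' @export
evaluate_model <- function(object, examples, threshold = 0.5) {
  model <- if (inherits(object, "dti_fit")) object$model else object
  p <- predict_proba(model, examples)
  rf <- recall_f1(p, examples$label, threshold)
  list(roc_auc = roc_auc(p, examples$label),
       pr_auc = pr_auc(p, examples$label),
       recall = rf$recall, f1 = rf$f1, n = nrow(examples))
}

#' Aggregate metric reports over repeated runs
#'
#' @param reports List of metric records (as from [evaluate_model()]).
#' @return List with per-metric `mean`, `sd` (sample standard deviation,
#'   0 for a single run), `n_runs`, and a `pretty` rendering in the
#'   conventional "mean +/- sd" 3-decimal style.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) < 1L) stop("need at least one report")
  metrics <- c("roc_auc", "pr_auc", "recall", "f1")
  vals <- sapply(metrics, function(m)
    vapply(reports, function(r) as.numeric(r[[m]]), numeric(1)))
  vals <- matrix(vals, nrow = length(reports),
                 dimnames = list(NULL, metrics))
  mean_ <- colMeans(vals)
  sd_ <- if (nrow(vals) > 1L) apply(vals, 2L, stats::sd) else
    stats::setNames(rep(0, length(metrics)), metrics)
  pretty <- sprintf("%.3f ± %.3f", mean_, sd_)
  names(pretty) <- metrics
  list(mean = as.list(mean_), sd = as.list(sd_),
       n_runs = length(reports), pretty = pretty)
}

#' Ablation variant configurations
#'
#' Maps a named architecture ablation to a concrete [model_config()]
#' delta: `"full"` (both modalities, cross-attention on),
#' `"image+smiles"` (text channel fed raw SMILES characters),
#' `"text"` / `"image"` (single modality), `"-mca"` (cross-attention
#' removed), and the compositions `"-mca-image"` (text only, no
#' cross-attention) and `"-mca-text"` (image only, no cross-attention).
#'
#' @param name Variant name.
#' @param base Base configuration the delta is applied to.
#' @return A [model_config()].
#' @export
build_ablation <- function(name, base = model_config()) {
  deltas <- list(
    "full" = list(),
    "image+smiles" = list(text_source = "smiles"),
    "text" = list(modalities = "text"),
    "image" = list(modalities = "image"),
    "-mca" = list(use_mca = FALSE),
    "-mca-image" = list(modalities = "text", use_mca = FALSE),
    "-mca-text" = list(modalities = "image", use_mca = FALSE))
  if (!name %in% names(deltas))
    stop_config("unknown ablation variant '", name, "'")
  cfg <- base
  for (k in names(deltas[[name]])) cfg[[k]] <- deltas[[name]][[k]]
  # re-validate through the constructor
  do.call(model_config, cfg[setdiff(names(cfg), "n_img_tokens")])
}
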