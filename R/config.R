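#' Model architecture configuration
#'
#' Collects every architecture hyperparameter of the interaction model:
#' image side and backbone channels, embedding width, attention geometry,
#' token lengths, the modality-combination weights, and the ablation
#' switches (modalities, cross-attention on/off).
#'
#' Defaults are desk-scale so that the full pipeline trains in minutes on a
#' single CPU; every size is configurable up to paper-scale backbones
#' (e.g. `h = 224`, `d_model = 256`).
#'
#' @param h Image side in pixels; must be divisible by 16 (the backbone
#'   downsamples by 2 in each of its four stages).
#' @param channels Integer vector of four backbone stage widths.
#' @param d_model Embedding/attention width; divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param depth Number of self-attention layers per encoder/decoder block.
#' @param mlp_ratio Hidden expansion factor of the transformer MLPs.
#' @param dropout Dropout rate in [0, 1), applied after attention and MLP
#'   sublayers during training.
#' @param L_drug Token length of the drug chemical-text stream.
#' @param L_tgt Token length of the target stream.
#' @param k_drug k-gram length for drug chemical text.
#' @param k_tgt k-gram length for target sequences (single residues by
#'   default; overlapping 3-mers via `k_tgt = 3`).
#' @param lambda_mode `"learnable"` (scalars trained from `lambda_init`) or
#'   `"fixed"` (frozen at `lambda_init`).
#' @param lambda_init Length-2 numeric, initial \eqn{(\lambda_1, \lambda_2)}
#'   weights of image and text modalities.
#' @param modalities Character subset of `c("image", "text")`.
#' @param text_source `"chemical"` (pharmacophore text) or `"smiles"` (raw
#'   SMILES characters; the image+SMILES ablation).
#' @param use_mca Logical; `FALSE` removes the cross-attention block from
#'   both decoders (decoders reduce to self-attention only).
#' @param mca_query_source `"self"` (queries from the decoder's own stream,
#'   keys/values from the other entity) or `"other"` (flipped).
#' @param fusion_conv2d_channels,fusion_conv1d_channels,fusion_hidden Fusion
#'   head sizes: 3x3 Conv2D channels, kernel-3 Conv1D channels, MLP hidden
#'   width.
#' @param task `"dti"` (drug-protein) or `"ddi"` (drug-drug; the partner is
#'   a second SMILES encoded by the same multimodal drug encoder).
#' @return An object of class `model_config` (a named list).
#' @export
model_config <- function(h = 32L,
                         channels = c(6L, 12L, 24L, 48L),
                         d_model = 24L,
                         n_heads = 4L,
                         depth = 1L,
                         mlp_ratio = 2,
                         dropout = 0.1,
                         L_drug = 32L,
                         L_tgt = 32L,
                         k_drug = 1L,
                         k_tgt = 1L,
                         lambda_mode = c("learnable", "fixed"),
                         lambda_init = c(1, 1),
                         modalities = c("image", "text"),
                         text_source = c("chemical", "smiles"),
                         use_mca = TRUE,
                         mca_query_source = c("self", "other"),
                         fusion_conv2d_channels = 8L,
                         fusion_conv1d_channels = 16L,
                         fusion_hidden = 64L,
                         task = c("dti", "ddi")) {
  lambda_mode <- match.arg(lambda_mode)
  text_source <- match.arg(text_source)
  mca_query_source <- match.arg(mca_query_source)
  task <- match.arg(task)
  modalities <- match.arg(modalities, c("image", "text"), several.ok = TRUE)
  if (h %% 16L != 0L)
    stop_config("image side h = ", h, " must be divisible by 16")
  if (length(channels) != 4L)
    stop_config("backbone needs exactly 4 stage widths")
  if (d_model %% n_heads != 0L)
    stop_config("d_model (", d_model, ") must be divisible by n_heads (",
                n_heads, ")")
  if (dropout < 0 || dropout >= 1)
    stop_config("dropout must lie in [0, 1)")
  if (length(modalities) < 1L)
    stop_config("at least one modality must be enabled")
  if (length(lambda_init) != 2L || any(!is.finite(lambda_init)))
    stop_config("lambda_init must be two finite numbers")
  cfg <- list(h = as.integer(h), channels = as.integer(channels),
              d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              depth = as.integer(depth), mlp_ratio = mlp_ratio,
              dropout = dropout,
              L_drug = as.integer(L_drug), L_tgt = as.integer(L_tgt),
              k_drug = as.integer(k_drug), k_tgt = as.integer(k_tgt),
              lambda_mode = lambda_mode, lambda_init = as.numeric(lambda_init),
              modalities = modalities, text_source = text_source,
              use_mca = isTRUE(use_mca), mca_query_source = mca_query_source,
              fusion_conv2d_channels = as.integer(fusion_conv2d_channels),
              fusion_conv1d_channels = as.integer(fusion_conv1d_channels),
              fusion_hidden = as.integer(fusion_hidden),
              task = task)
  cfg$n_img_tokens <- as.integer((h %/% 16L)^2)
  class(cfg) <- "model_config"
  cfg
}

#' Optimisation configuration
#'
#' @param lr Initial Adam learning rate (> 0).
#' @param lr_decay Multiplicative decay factor in (0, 1].
#' @param decay_every Epoch cadence of the decay (the decay factor from the
#'   original protocol is applied every `decay_every` epochs).
#' @param batch_size Mini-batch size.
#' @param epochs Number of training epochs.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout; identical seeds reproduce runs exactly.
#' @param checkpoint_metric Validation metric used for best-epoch model
#'   selection; only `"roc_auc"` is supported.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, lr_decay = 0.8, decay_every = 10L,
                         batch_size = 128L, epochs = 100L, seed = 0L,
                         checkpoint_metric = "roc_auc") {
  if (lr <= 0) stop_config("lr must be > 0")
  if (lr_decay <= 0 || lr_decay > 1) stop_config("lr_decay must be in (0, 1]")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (!identical(checkpoint_metric, "roc_auc"))
    stop_config("only roc_auc checkpointing is supported")
  structure(list(lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_metric = checkpoint_metric),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr * lr_decay^floor(epoch / decay_every)` with epochs
#' counted from 0. Monotone non-increasing in `epoch`.
#'
#' @param epoch Zero-based epoch index.
#' @param cfg A [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_at <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  cfg$lr * cfg$lr_decay^(epoch %/% cfg$decay_every)
}
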