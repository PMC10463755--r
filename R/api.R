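# Public wrappers over the network internals: single-example forward
# passes used for inspection, contract tests and documentation examples.

#' Image tokens from the convolutional backbone
#'
#' Renders (or accepts) a molecular image and runs it through the
#' four-stage conv/batch-norm/ReLU/max-pool backbone, returning the
#' flattened spatial cells projected to model width (inference mode).
#'
#' @param model A `dti_model` with the image modality enabled.
#' @param smiles SMILES string to render; alternatively pass `image`.
#' @param image Optional `h x h x 3` array overriding `smiles`.
#' @return A `(h/16)^2 x d_model` matrix of image tokens.
#' @export
conv_backbone <- function(model, smiles = NULL, image = NULL) {
  cfg <- model$cfg
  if (!"image" %in% cfg$modalities)
    stop_config("image modality is disabled in this model")
  if (is.null(image)) image <- render_image(smiles, cfg$h)
  if (!all(dim(image) == c(cfg$h, cfg$h, 3L)))
    stop_config("image must be ", cfg$h, "x", cfg$h, "x3")
  r <- conv_backbone_fwd(model$params, model$buffers, model$plans, cfg,
                         img_to_rows(image), B = 1L, train = FALSE)
  r$out
}

#' Combine image and text modality features
#'
#' Element-wise weighted sum `lambda1 * X_img + lambda2 * X_txt` after
#' bringing both maps to a common token length: image tokens are
#' resampled along the token axis by adaptive averaging to the text
#' length. Passing a single modality returns it unchanged (ablation
#' pass-through).
#'
#' @param X_img Image feature map (tokens x d) or `NULL`.
#' @param X_txt Text feature map (tokens x d) or `NULL`.
#' @param lambda1,lambda2 Modality weights.
#' @return The combined feature map.
#' @export
combine_modalities <- function(X_img, X_txt, lambda1 = 1, lambda2 = 1) {
  if (is.null(X_img) && is.null(X_txt))
    stop_config("at least one modality map required")
  if (is.null(X_txt)) return(X_img)
  if (is.null(X_img)) return(X_txt)
  if (nrow(X_img) != nrow(X_txt)) {
    A <- resample_matrix(nrow(X_img), nrow(X_txt))
    X_img <- A %*% X_img
  }
  lambda1 * X_img + lambda2 * X_txt
}

#' Multi-head attention forward pass (single example)
#'
#' Queries are projected from `Xq`, keys and values from `Xkv` (equal to
#' `Xq` for self-attention). Masked key positions receive zero attention.
#'
#' @param Xq Query-side feature map (`Lq x d`).
#' @param Xkv Key/value-side feature map (`Lk x d`).
#' @param p Attention parameters, as from [attn_params()].
#' @param n_heads Number of heads (`d` divisible by it).
#' @param mask Logical length-`Lk` vector, `TRUE` = valid key (default all).
#' @return List with `out` (`Lq x d`) and `attention`
#'   (`Lq x Lk x n_heads` array of probability rows).
#' @export
mha_forward <- function(Xq, Xkv = Xq, p, n_heads, mask = NULL) {
  d <- ncol(Xq)
  if (d %% n_heads != 0L) stop_config("d must be divisible by n_heads")
  if (is.null(mask)) mask <- rep(TRUE, nrow(Xkv))
  r <- mha_fwd(Xq, Xkv, p, n_heads, matrix(mask, 1L), B = 1L,
               Lq = nrow(Xq), Lk = nrow(Xkv))
  A <- r$cache$A
  list(out = r$out, attention = array(A, dim = dim(A)[1:3]))
}

#' Attention parameter initialisers
#'
#' Draw fresh attention / attention-layer parameters using the caller's
#' RNG state; use `set.seed()` for reproducibility.
#'
#' @param d Model width.
#' @param mlp_ratio MLP hidden expansion for layer initialisers.
#' @return A parameter list.
#' @export
attn_params <- function(d) init_attn_params(d)

#' @rdname attn_params
#' @export
msa_layer_params <- function(d, mlp_ratio = 2) init_msa_layer(d, mlp_ratio)

#' @rdname attn_params
#' @export
mca_layer_params <- function(d, mlp_ratio = 2) init_mca_layer(d, mlp_ratio)

#' Pre-norm self-attention block (single example, inference)
#'
#' `x + MHA(LN(x))` followed by `+ MLP(LN(.))`; padded positions are
#' excluded as attention keys through `mask`.
#'
#' @param x `L x d` feature map.
#' @param p Layer parameters from [msa_layer_params()].
#' @param n_heads Heads.
#' @param mask Logical length-`L` valid-key mask (default all valid).
#' @return List with `out` (`L x d`) and `attention` array.
#' @export
msa_forward <- function(x, p, n_heads, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(x))
  r <- msa_layer_fwd(x, p, n_heads, matrix(mask, 1L), B = 1L, L = nrow(x))
  list(out = r$out, attention = array(r$attn, dim = dim(r$attn)[1:3]))
}

#' Pre-norm cross-attention block (single example, inference)
#'
#' Same skeleton as [msa_forward()] but queries come from `stream` and
#' keys/values from `other`; the output keeps `stream`'s length.
#'
#' @param stream Query-side map (`Ls x d`).
#' @param other Key/value-side map (`Lo x d`).
#' @param p Layer parameters from [mca_layer_params()].
#' @param n_heads Heads.
#' @param mask_other Logical length-`Lo` valid-key mask.
#' @return List with `out` (`Ls x d`) and `attention` array.
#' @export
mca_forward <- function(stream, other, p, n_heads, mask_other = NULL) {
  if (is.null(mask_other)) mask_other <- rep(TRUE, nrow(other))
  r <- mca_layer_fwd(stream, other, p, n_heads, matrix(mask_other, 1L),
                     B = 1L, Ls = nrow(stream), Lo = nrow(other))
  list(out = r$out, attention = array(r$attn, dim = dim(r$attn)[1:3]))
}

#' Decoder interaction maps for one pair
#'
#' Runs the full encoder/decoder stack in inference mode for a single
#' (drug, partner) pair and returns the two decoder output feature maps
#' exchanged through cross-attention, plus the fused interaction
#' probability.
#'
#' @param model A trained or freshly initialised `dti_model`.
#' @param drug_smiles Drug SMILES.
#' @param partner Protein sequence (DTI) or second SMILES (DDI).
#' @return List `Z_dt`, `Z_td` (feature maps) and `p` (probability).
#' @export
interaction_maps <- function(model, drug_smiles, partner) {
  ex <- data.frame(drug_smiles = drug_smiles, partner = partner, label = 0L)
  store <- build_feature_store(model$cfg, ex, model$vocab_txt,
                               model$vocab_tgt)
  fwd <- model_forward(model, make_batch(store, ex), train = FALSE)
  list(Z_dt = fwd$Z_dt, Z_td = fwd$Z_td, p = fwd$p)
}

#' Predict interaction probabilities
#'
#' @param model A `dti_model` (typically the best checkpoint from
#'   [train_model()]).
#' @param examples Example data frame (`drug_smiles`, `partner`, ...).
#' @param batch_size Mini-batch size for the forward passes.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, examples, batch_size = 128L) {
  store <- build_feature_store(model$cfg, examples, model$vocab_txt,
                               model$vocab_tgt)
  n <- nrow(examples)
  p <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fwd <- model_forward(model, make_batch(store, examples[i:j, , drop = FALSE]),
                         train = FALSE)
    p[i:j] <- fwd$p
    i <- j + 1L
  }
  p
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file embedding the full architecture
#' configuration, vocabularies, parameters and normalisation buffers.
#'
#' @param model A `dti_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  obj <- model[c("cfg", "vocab_txt", "vocab_tgt", "params", "buffers")]
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  m <- structure(obj, class = "dti_model")
  m$plans <- build_plans(m$cfg)
  m
}

#' @export
print.dti_model <- function(x, ...) {
  cfg <- x$cfg
  cat("Interaction model (", cfg$task, "): d_model=", cfg$d_model,
      ", heads=", cfg$n_heads, ", modalities=",
      paste(cfg$modalities, collapse = "+"),
      ", cross-attention=", cfg$use_mca,
      ", parameters=", param_count(x), "\n", sep = "")
  invisible(x)
}
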