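# Featurisation cache: every unique SMILES / protein in a dataset is
# rendered and tokenised exactly once; batches gather rows from the store.

img_to_rows <- function(img) {
  # h x h x c array -> (h*h) x c matrix, rows ordered (y, x)
  h <- dim(img)[1L]; cmat <- matrix(0, h * h, dim(img)[3L])
  for (ch in seq_len(dim(img)[3L])) cmat[, ch] <- as.vector(t(img[, , ch]))
  cmat
}

build_feature_store <- function(cfg, examples, vocab_txt, vocab_tgt) {
  use_img <- "image" %in% cfg$modalities
  use_txt <- "text" %in% cfg$modalities
  drugs <- unique(c(examples$drug_smiles,
                    if (cfg$task == "ddi") examples$partner))
  n_d <- length(drugs)
  store <- list(cfg = cfg, drug_ids = stats::setNames(seq_len(n_d), drugs))
  if (use_img) {
    hh <- cfg$h * cfg$h
    img_mat <- matrix(0, n_d * hh, 3L)
    for (i in seq_len(n_d)) {
      img_mat[((i - 1L) * hh + 1L):(i * hh), ] <-
        img_to_rows(render_image(drugs[i], cfg$h))
    }
    store$img_mat <- img_mat
  }
  if (use_txt) {
    txt_idx <- matrix(0L, n_d, cfg$L_drug)
    txt_valid <- matrix(FALSE, n_d, cfg$L_drug)
    for (i in seq_len(n_d)) {
      ts <- encode_tokens(drug_text_phrases(drugs[i], cfg), vocab_txt,
                          cfg$L_drug)
      txt_idx[i, ] <- ts$indices
      txt_valid[i, ] <- !ts$pad_mask
      if (!any(txt_valid[i, ])) txt_valid[i, 1L] <- TRUE  # featureless drug
    }
    store$txt_idx <- txt_idx; store$txt_valid <- txt_valid
  }
  if (cfg$task == "dti") {
    tgts <- unique(examples$partner)
    store$tgt_ids <- stats::setNames(seq_along(tgts), tgts)
    tgt_idx <- matrix(0L, length(tgts), cfg$L_tgt)
    tgt_valid <- matrix(FALSE, length(tgts), cfg$L_tgt)
    for (i in seq_along(tgts)) {
      ts <- featurize_protein(tgts[i], vocab_tgt, cfg$k_tgt, cfg$L_tgt)
      tgt_idx[i, ] <- ts$indices
      tgt_valid[i, ] <- !ts$pad_mask
      if (!any(tgt_valid[i, ])) tgt_valid[i, 1L] <- TRUE
    }
    store$tgt_idx <- tgt_idx; store$tgt_valid <- tgt_valid
  }
  store
}

gather_drug_inputs <- function(store, cfg, di) {
  B <- length(di)
  out <- list()
  if ("image" %in% cfg$modalities) {
    hh <- cfg$h * cfg$h
    rows <- as.vector(vapply(di, function(i) ((i - 1L) * hh + 1L):(i * hh),
                             integer(hh)))
    out$imgs <- store$img_mat[rows, , drop = FALSE]
  }
  if ("text" %in% cfg$modalities) {
    out$txt_idx <- store$txt_idx[di, , drop = FALSE]
    out$txt_mask <- store$txt_valid[di, , drop = FALSE]
  }
  out
}

make_batch <- function(store, examples) {
  cfg <- store$cfg
  di <- unname(store$drug_ids[examples$drug_smiles])
  b <- gather_drug_inputs(store, cfg, di)
  if (cfg$task == "dti") {
    pi <- unname(store$tgt_ids[examples$partner])
    b$tgt_idx <- store$tgt_idx[pi, , drop = FALSE]
    b$tgt_mask <- store$tgt_valid[pi, , drop = FALSE]
  } else {
    di2 <- unname(store$drug_ids[examples$partner])
    b2 <- gather_drug_inputs(store, cfg, di2)
    b$imgs2 <- b2$imgs; b$txt_idx2 <- b2$txt_idx; b$txt_mask2 <- b2$txt_mask
  }
  b$y <- examples$label
  b$B <- nrow(examples)
  b
}

# Fit first-appearance vocabularies on a training split.
fit_vocabs <- function(cfg, train_set) {
  vocab_txt <- NULL; vocab_tgt <- NULL
  if ("text" %in% cfg$modalities) {
    drugs <- unique(c(train_set$drug_smiles,
                      if (cfg$task == "ddi") train_set$partner))
    vocab_txt <- build_vocab(lapply(drugs, drug_text_phrases, cfg = cfg),
                             k = cfg$k_drug)
  }
  if (cfg$task == "dti") {
    tgts <- unique(train_set$partner)
    vocab_tgt <- build_vocab(lapply(tgts, protein_phrases, cfg = cfg),
                             k = cfg$k_tgt)
  }
  list(txt = vocab_txt, tgt = vocab_tgt)
}
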