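# Small shared fixtures, built in code at test time.

tiny_model_cfg <- function(...) {
  defaults <- list(h = 32L, channels = c(2L, 3L, 4L, 5L), d_model = 8L,
                   n_heads = 2L, depth = 1L, mlp_ratio = 2, dropout = 0,
                   L_drug = 6L, L_tgt = 5L, k_drug = 1L, k_tgt = 1L,
                   fusion_conv2d_channels = 2L, fusion_conv1d_channels = 3L,
                   fusion_hidden = 7L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_vocabs <- function() {
  list(txt = build_vocab(list(c("A", "B", "C", "D"))),
       tgt = build_vocab(list(c("M", "K", "V", "H"))))
}

tiny_batch <- function(cfg, B = 2L, seed = 7L) {
  withr::with_seed(seed, list(
    imgs = matrix(runif(B * cfg$h * cfg$h * 3), ncol = 3),
    txt_idx = matrix(sample(0:5, B * cfg$L_drug, TRUE), B),
    txt_mask = matrix(rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                          length.out = B * cfg$L_drug), B, byrow = TRUE),
    tgt_idx = matrix(sample(0:5, B * cfg$L_tgt, TRUE), B),
    tgt_mask = matrix(TRUE, B, cfg$L_tgt),
    y = rep_len(c(1, 0), B), B = B))
}

example_frame <- function(drug, partner, label, task = "dti") {
  out <- data.frame(drug_smiles = drug, partner = partner,
                    label = as.integer(label), stringsAsFactors = FALSE)
  attr(out, "task") <- task
  out
}
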