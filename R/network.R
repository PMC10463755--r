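# Model assembly: multimodal drug encoder (CNN backbone + chemical-text
# embedding, combined with learnable scalar weights), target encoder,
# bi-directional cross-attention decoders and the convolutional fusion
# head, with a full hand-written backward pass.

#' Construct an interaction model
#'
#' Initialises all trainable parameters of the drug-target (or drug-drug)
#' interaction network for a given architecture configuration and fitted
#' vocabularies. Initialisation is seeded and reproducible.
#'
#' @param cfg A [model_config()].
#' @param vocab_txt Drug-text `kgram_vocab` (required when the text
#'   modality is enabled).
#' @param vocab_tgt Target `kgram_vocab` (required for the DTI task; the
#'   DDI task re-uses the drug encoder for the partner).
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `dti_model`.
#' @export
dti_model <- function(cfg, vocab_txt = NULL, vocab_tgt = NULL, seed = 0L) {
  use_img <- "image" %in% cfg$modalities
  use_txt <- "text" %in% cfg$modalities
  if (use_txt && is.null(vocab_txt))
    stop_config("text modality enabled but vocab_txt missing")
  if (cfg$task == "dti" && is.null(vocab_tgt))
    stop_config("DTI task requires vocab_tgt")
  d <- cfg$d_model
  params <- with_seed(seed, {
    p <- list()
    if (use_img) {
      chans <- c(3L, cfg$channels)
      p$conv <- list(stages = lapply(1:4, function(s) {
        list(W = init_glorot(9L * chans[s], chans[s + 1L]) *
               sqrt(2),  # He-flavoured gain for ReLU stages
             b = rep(0, chans[s + 1L]),
             bn_g = rep(1, chans[s + 1L]), bn_b = rep(0, chans[s + 1L]))
      }),
      proj = list(W = init_glorot(cfg$channels[4L], d), b = rep(0, d)))
      p$pos_img <- matrix(stats::rnorm(cfg$n_img_tokens * d, 0, 0.02),
                          cfg$n_img_tokens, d)
      p$img_msa <- lapply(seq_len(cfg$depth), function(i)
        init_msa_layer(d, cfg$mlp_ratio))
    }
    if (use_txt) {
      p$emb_txt <- matrix(stats::rnorm(vocab_size(vocab_txt) * d, 0, 0.1),
                          vocab_size(vocab_txt), d)
      p$pos_txt <- matrix(stats::rnorm(cfg$L_drug * d, 0, 0.02),
                          cfg$L_drug, d)
      p$txt_msa <- lapply(seq_len(cfg$depth), function(i)
        init_msa_layer(d, cfg$mlp_ratio))
    }
    if (use_img && use_txt) p$lambda <- as.numeric(cfg$lambda_init)
    if (cfg$task == "dti") {
      p$emb_tgt <- matrix(stats::rnorm(vocab_size(vocab_tgt) * d, 0, 0.1),
                          vocab_size(vocab_tgt), d)
      p$pos_tgt <- matrix(stats::rnorm(cfg$L_tgt * d, 0, 0.02), cfg$L_tgt, d)
      p$tgt_msa <- lapply(seq_len(cfg$depth), function(i)
        init_msa_layer(d, cfg$mlp_ratio))
    }
    p$dec_drug <- list(msa = lapply(seq_len(cfg$depth), function(i)
      init_msa_layer(d, cfg$mlp_ratio)))
    p$dec_tgt <- list(msa = lapply(seq_len(cfg$depth), function(i)
      init_msa_layer(d, cfg$mlp_ratio)))
    if (cfg$use_mca) {
      p$dec_drug$mca <- lapply(seq_len(cfg$depth), function(i)
        init_mca_layer(d, cfg$mlp_ratio))
      p$dec_tgt$mca <- lapply(seq_len(cfg$depth), function(i)
        init_mca_layer(d, cfg$mlp_ratio))
    }
    L_ds <- drug_stream_length(cfg)
    L_ts <- target_stream_length(cfg)
    L_fuse <- min(L_ds, L_ts)
    C2 <- cfg$fusion_conv2d_channels; C3 <- cfg$fusion_conv1d_channels
    p$fuse <- list(
      conv2d = list(W = init_glorot(9L * 2L, C2) * sqrt(2), b = rep(0, C2)),
      conv1d = list(W = init_glorot(3L * C2, C3) * sqrt(2), b = rep(0, C3)),
      mlp = list(W1 = init_glorot(d * C3, cfg$fusion_hidden),
                 b1 = rep(0, cfg$fusion_hidden)),
      fc = list(W = init_glorot(cfg$fusion_hidden, 1L), b = 0))
    p
  })
  buffers <- NULL
  if (use_img) {
    buffers <- list(conv = lapply(cfg$channels, function(cc)
      list(mu = rep(0, cc), var = rep(1, cc))))
  }
  m <- structure(list(cfg = cfg, vocab_txt = vocab_txt, vocab_tgt = vocab_tgt,
                      params = params, buffers = buffers),
                 class = "dti_model")
  m$plans <- build_plans(cfg)
  m
}

# Stream lengths after modality combination.
drug_stream_length <- function(cfg) {
  use_img <- "image" %in% cfg$modalities
  use_txt <- "text" %in% cfg$modalities
  if (use_txt) cfg$L_drug else cfg$n_img_tokens
}

target_stream_length <- function(cfg) {
  if (cfg$task == "dti") {
    cfg$L_tgt
  } else drug_stream_length(cfg)
}

build_plans <- function(cfg) {
  plans <- list()
  if ("image" %in% cfg$modalities) {
    h <- cfg$h
    sides <- h %/% c(1L, 2L, 4L, 8L)
    plans$conv <- lapply(sides, function(s) conv_plan(s, s))
    plans$pool <- lapply(sides, function(s) pool_plan(s, s))
    if ("text" %in% cfg$modalities)
      plans$A_img <- resample_matrix(cfg$n_img_tokens, cfg$L_drug)
  }
  L_ds <- drug_stream_length(cfg)
  L_ts <- target_stream_length(cfg)
  L_fuse <- min(L_ds, L_ts)
  plans$L_ds <- L_ds; plans$L_ts <- L_ts; plans$L_fuse <- L_fuse
  plans$A_fd <- resample_matrix(L_ds, L_fuse)
  plans$A_ft <- resample_matrix(L_ts, L_fuse)
  plans$conv2d <- conv_plan(L_fuse, cfg$d_model)
  plans$conv1d <- conv_plan(cfg$d_model, 1L, kh = 3L, kw = 1L)
  plans
}

#' Count trainable parameters
#'
#' @param x A `dti_model` or a raw parameter list.
#' @return Total number of scalar trainable parameters.
#' @export
param_count <- function(x) {
  p <- if (inherits(x, "dti_model")) x$params else x
  sum(unlist(lapply(p, function(e) {
    if (is.list(e)) param_count(e) else length(e)
  })))
}

# ---- encoder pieces -------------------------------------------------------

# imgs: (B*h*h) x 3 matrix. Returns (B*T) x d tokens.
conv_backbone_fwd <- function(params, buffers, plans, cfg, imgs, B,
                              train = FALSE) {
  x <- imgs
  caches <- vector("list", 4L)
  for (s in 1:4) {
    st <- params$conv$stages[[s]]
    cv <- conv_fwd(x, st$W, st$b, plans$conv[[s]], B)
    bn <- bn_fwd(cv$out, st$bn_g, st$bn_b,
                 buffers$conv[[s]]$mu, buffers$conv[[s]]$var, train)
    buffers$conv[[s]]$mu <- bn$run_mu
    buffers$conv[[s]]$var <- bn$run_var
    rl <- relu_fwd(bn$out)
    pl <- pool_fwd(rl$out, plans$pool[[s]], B)
    caches[[s]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache,
                        pl = pl$cache)
    x <- pl$out
  }
  pj <- lin_fwd(x, params$conv$proj$W, params$conv$proj$b)
  list(out = pj$out, buffers = buffers,
       cache = list(stages = caches, proj = pj$cache))
}

conv_backbone_bwd <- function(dout, params, cache) {
  gp <- lin_bwd(dout, cache$proj)
  dx <- gp$dx
  grads <- list(stages = vector("list", 4L),
                proj = list(W = gp$dW, b = gp$db))
  for (s in 4:1) {
    cc <- cache$stages[[s]]
    dpl <- pool_bwd(dx, cc$pl)
    drl <- relu_bwd(dpl, cc$rl)
    gbn <- bn_bwd(drl, cc$bn)
    gcv <- conv_bwd(gbn$dx, cc$cv)
    grads$stages[[s]] <- list(W = gcv$dW, b = gcv$db,
                              bn_g = gbn$dg, bn_b = gbn$db)
    dx <- gcv$dx
  }
  list(dimgs = dx, grads = grads)
}

run_msa_stack <- function(x, layers, H, mask, B, L, rate, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- msa_layer_fwd(x, layers[[i]], H, mask, B, L, rate, train)
    x <- r$out; caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

bwd_msa_stack <- function(dout, layers, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    g <- msa_layer_bwd(dout, caches[[i]])
    grads[[i]] <- g$grads
    dout <- g$dx
  }
  list(dx = dout, grads = grads)
}

run_mca_stack <- function(stream, other, layers, H, mask_other, B, Ls, Lo,
                          rate, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- mca_layer_fwd(stream, other, layers[[i]], H, mask_other, B, Ls, Lo,
                       rate, train)
    stream <- r$out; caches[[i]] <- r$cache
  }
  list(out = stream, caches = caches)
}

bwd_mca_stack <- function(dout, layers, caches, Lo, B, d) {
  grads <- vector("list", length(layers))
  dother <- matrix(0, B * Lo, d)
  for (i in rev(seq_along(layers))) {
    g <- mca_layer_bwd(dout, caches[[i]])
    grads[[i]] <- g$grads
    dother <- dother + g$dother
    dout <- g$dstream
  }
  list(dstream = dout, dother = dother, grads = grads)
}

# Multimodal drug encoder. Returns the combined drug stream.
encode_drug_fwd <- function(params, buffers, plans, cfg, imgs, txt_idx,
                            txt_mask, B, train) {
  use_img <- "image" %in% cfg$modalities
  use_txt <- "text" %in% cfg$modalities
  d <- cfg$d_model
  cache <- list()
  X_img <- NULL
  if (use_img) {
    cb <- conv_backbone_fwd(params, buffers, plans, cfg, imgs, B, train)
    buffers <- cb$buffers
    tok <- cb$out + params$pos_img[rep(seq_len(cfg$n_img_tokens), B), ]
    mask_img <- matrix(TRUE, B, cfg$n_img_tokens)
    ms <- run_msa_stack(tok, params$img_msa, cfg$n_heads, mask_img, B,
                        cfg$n_img_tokens, cfg$dropout, train)
    X_img <- ms$out
    cache$img <- list(cb = cb$cache, msa = ms$caches)
  }
  X_txt <- NULL
  if (use_txt) {
    em <- emb_fwd(txt_idx, params$emb_txt)
    tok <- em$out + params$pos_txt[rep(seq_len(cfg$L_drug), B), ]
    ms <- run_msa_stack(tok, params$txt_msa, cfg$n_heads, txt_mask, B,
                        cfg$L_drug, cfg$dropout, train)
    X_txt <- ms$out
    cache$txt <- list(em = em$cache, msa = ms$caches)
  }
  if (use_img && use_txt) {
    X_img_al <- resample_fwd(X_img, plans$A_img, B, cfg$n_img_tokens)
    lam <- params$lambda
    X <- lam[1L] * X_img_al + lam[2L] * X_txt
    cache$comb <- list(X_img_al = X_img_al, X_txt = X_txt, lam = lam)
    mask <- matrix(TRUE, B, cfg$L_drug)
    L <- cfg$L_drug
  } else if (use_img) {
    X <- X_img; mask <- matrix(TRUE, B, cfg$n_img_tokens)
    L <- cfg$n_img_tokens
  } else {
    X <- X_txt; mask <- txt_mask; L <- cfg$L_drug
  }
  list(out = X, mask = mask, L = L, buffers = buffers, cache = cache)
}

encode_drug_bwd <- function(dX, params, plans, cfg, cache, B) {
  use_img <- "image" %in% cfg$modalities
  use_txt <- "text" %in% cfg$modalities
  grads <- list()
  dX_img <- NULL; dX_txt <- NULL
  if (use_img && use_txt) {
    cb <- cache$comb
    grads$lambda <- c(sum(dX * cb$X_img_al), sum(dX * cb$X_txt))
    dX_img <- resample_bwd(cb$lam[1L] * dX, plans$A_img, B,
                           cfg$n_img_tokens)
    dX_txt <- cb$lam[2L] * dX
  } else if (use_img) dX_img <- dX else dX_txt <- dX
  if (use_txt) {
    g <- bwd_msa_stack(dX_txt, params$txt_msa, cache$txt$msa)
    grads$txt_msa <- g$grads
    dtok <- g$dx
    grads$pos_txt <- rowsum(dtok, group = rep(seq_len(cfg$L_drug), B))
    ge <- emb_bwd(dtok, cache$txt$em)
    grads$emb_txt <- ge$dW
  }
  dimgs <- NULL
  if (use_img) {
    g <- bwd_msa_stack(dX_img, params$img_msa, cache$img$msa)
    grads$img_msa <- g$grads
    dtok <- g$dx
    grads$pos_img <- rowsum(dtok, group = rep(seq_len(cfg$n_img_tokens), B))
    gc <- conv_backbone_bwd(dtok, params, cache$img$cb)
    grads$conv <- gc$grads
    dimgs <- gc$dimgs
  }
  list(grads = grads, dimgs = dimgs)
}

encode_target_fwd <- function(params, plans, cfg, tgt_idx, tgt_mask, B,
                              train) {
  em <- emb_fwd(tgt_idx, params$emb_tgt)
  tok <- em$out + params$pos_tgt[rep(seq_len(cfg$L_tgt), B), ]
  ms <- run_msa_stack(tok, params$tgt_msa, cfg$n_heads, tgt_mask, B,
                      cfg$L_tgt, cfg$dropout, train)
  list(out = ms$out, cache = list(em = em$cache, msa = ms$caches))
}

encode_target_bwd <- function(dX, params, cfg, cache, B) {
  g <- bwd_msa_stack(dX, params$tgt_msa, cache$msa)
  dtok <- g$dx
  ge <- emb_bwd(dtok, cache$em)
  list(grads = list(tgt_msa = g$grads,
                    pos_tgt = rowsum(dtok, group = rep(seq_len(cfg$L_tgt), B)),
                    emb_tgt = ge$dW))
}

# ---- full forward / backward ----------------------------------------------

model_forward <- function(model, batch, train = FALSE) {
  cfg <- model$cfg; params <- model$params; plans <- model$plans
  B <- batch$B; d <- cfg$d_model; H <- cfg$n_heads
  ed <- encode_drug_fwd(params, model$buffers, plans, cfg, batch$imgs,
                        batch$txt_idx, batch$txt_mask, B, train)
  buffers <- ed$buffers
  if (cfg$task == "dti") {
    et <- encode_target_fwd(params, plans, cfg, batch$tgt_idx,
                            batch$tgt_mask, B, train)
    X_tgt <- et$out; mask_tgt <- batch$tgt_mask; L_ts <- cfg$L_tgt
    cache_tgt <- et$cache
  } else {
    et <- encode_drug_fwd(params, buffers, plans, cfg, batch$imgs2,
                          batch$txt_idx2, batch$txt_mask2, B, train)
    buffers <- et$buffers
    X_tgt <- et$out; mask_tgt <- et$mask; L_ts <- et$L
    cache_tgt <- et$cache
  }
  X_drug <- ed$out; mask_drug <- ed$mask; L_ds <- ed$L
  sd_ <- run_msa_stack(X_drug, params$dec_drug$msa, H, mask_drug, B, L_ds,
                       cfg$dropout, train)
  st_ <- run_msa_stack(X_tgt, params$dec_tgt$msa, H, mask_tgt, B, L_ts,
                       cfg$dropout, train)
  S_d <- sd_$out; S_t <- st_$out
  if (cfg$use_mca) {
    if (cfg$mca_query_source == "self") {
      mca_d <- run_mca_stack(S_d, S_t, params$dec_drug$mca, H, mask_tgt, B,
                             L_ds, L_ts, cfg$dropout, train)
      mca_t <- run_mca_stack(S_t, S_d, params$dec_tgt$mca, H, mask_drug, B,
                             L_ts, L_ds, cfg$dropout, train)
      Z_dt <- mca_d$out; Z_td <- mca_t$out
      Lz_d <- L_ds; Lz_t <- L_ts
    } else {
      mca_d <- run_mca_stack(S_t, S_d, params$dec_drug$mca, H, mask_drug, B,
                             L_ts, L_ds, cfg$dropout, train)
      mca_t <- run_mca_stack(S_d, S_t, params$dec_tgt$mca, H, mask_tgt, B,
                             L_ds, L_ts, cfg$dropout, train)
      Z_dt <- mca_d$out; Z_td <- mca_t$out
      Lz_d <- L_ts; Lz_t <- L_ds
    }
  } else {
    Z_dt <- S_d; Z_td <- S_t; Lz_d <- L_ds; Lz_t <- L_ts
    mca_d <- NULL; mca_t <- NULL
  }
  # fusion head
  L_fuse <- plans$L_fuse
  A_zd <- if (ncol(plans$A_fd) == Lz_d) plans$A_fd else plans$A_ft
  A_zt <- if (ncol(plans$A_ft) == Lz_t) plans$A_ft else plans$A_fd
  Zd_r <- resample_fwd(Z_dt, A_zd, B, Lz_d)
  Zt_r <- resample_fwd(Z_td, A_zt, B, Lz_t)
  F0 <- cbind(as.vector(t(Zd_r)), as.vector(t(Zt_r)))
  cv2 <- conv_fwd(F0, params$fuse$conv2d$W, params$fuse$conv2d$b,
                  plans$conv2d, B)
  r2 <- relu_fwd(cv2$out)
  # row (b, y, x) -> group (b, x): token-axis mean collapse
  grp_full <- rep(seq_len(d), times = B * L_fuse) +
    rep((seq_len(B) - 1L) * d, each = L_fuse * d)
  M <- rowsum(r2$out, group = grp_full) / L_fuse
  cv1 <- conv_fwd(M, params$fuse$conv1d$W, params$fuse$conv1d$b,
                  plans$conv1d, B)
  r1 <- relu_fwd(cv1$out)
  C3 <- cfg$fusion_conv1d_channels
  arr <- array(r1$out, dim = c(d, B, C3))
  flat <- matrix(aperm(arr, c(2L, 3L, 1L)), nrow = B)
  m1 <- lin_fwd(flat, params$fuse$mlp$W1, params$fuse$mlp$b1)
  rm_ <- relu_fwd(m1$out)
  dp <- dropout_fwd(rm_$out, cfg$dropout, train)
  fc <- lin_fwd(dp$out, params$fuse$fc$W, params$fuse$fc$b)
  logits <- as.vector(fc$out)
  if (any(!is.finite(logits)))
    stop("non-finite activations in forward pass")
  p <- stats::plogis(logits)
  list(p = p, logits = logits, buffers = buffers,
       Z_dt = Z_dt, Z_td = Z_td, Lz_d = Lz_d, Lz_t = Lz_t,
       cache = list(ed = ed, cache_tgt = cache_tgt, sd = sd_$caches,
                    st = st_$caches, mca_d = mca_d, mca_t = mca_t,
                    A_zd = A_zd, A_zt = A_zt, Lz_d = Lz_d, Lz_t = Lz_t,
                    L_ds = L_ds, L_ts = L_ts,
                    mask_drug = mask_drug, mask_tgt = mask_tgt,
                    cv2 = cv2$cache, r2 = r2$cache, grp_full = grp_full,
                    L_fuse = L_fuse, cv1 = cv1$cache, r1 = r1$cache,
                    m1 = m1$cache, rm = rm_$cache, dp = dp$cache,
                    fc = fc$cache, B = B))
}

model_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg; params <- model$params; plans <- model$plans
  cc <- fwd$cache; B <- cc$B; d <- cfg$d_model; H <- cfg$n_heads
  C3 <- cfg$fusion_conv1d_channels
  grads <- list()
  gfc <- lin_bwd(matrix(dlogits, ncol = 1L), cc$fc)
  ddp <- dropout_bwd(gfc$dx, cc$dp)
  drm <- relu_bwd(ddp, cc$rm)
  gm1 <- lin_bwd(drm, cc$m1)
  grads$fuse <- list(fc = list(W = gfc$dW, b = gfc$db),
                     mlp = list(W1 = gm1$dW, b1 = gm1$db))
  dflat <- gm1$dx
  darr <- aperm(array(dflat, dim = c(B, C3, d)), c(3L, 1L, 2L))
  dr1 <- matrix(darr, ncol = C3)
  dcv1 <- relu_bwd(dr1, cc$r1)
  g1 <- conv_bwd(dcv1, cc$cv1)
  grads$fuse$conv1d <- list(W = g1$dW, b = g1$db)
  dM <- g1$dx
  dr2 <- dM[cc$grp_full, , drop = FALSE] / cc$L_fuse
  dcv2 <- relu_bwd(dr2, cc$r2)
  g2 <- conv_bwd(dcv2, cc$cv2)
  grads$fuse$conv2d <- list(W = g2$dW, b = g2$db)
  dF0 <- g2$dx
  dZd_r <- matrix(dF0[, 1L], ncol = d, byrow = TRUE)
  dZt_r <- matrix(dF0[, 2L], ncol = d, byrow = TRUE)
  dZ_dt <- resample_bwd(dZd_r, cc$A_zd, B, cc$Lz_d)
  dZ_td <- resample_bwd(dZt_r, cc$A_zt, B, cc$Lz_t)
  if (cfg$use_mca) {
    if (cfg$mca_query_source == "self") {
      gd <- bwd_mca_stack(dZ_dt, params$dec_drug$mca, cc$mca_d$caches,
                          cc$L_ts, B, d)
      gt <- bwd_mca_stack(dZ_td, params$dec_tgt$mca, cc$mca_t$caches,
                          cc$L_ds, B, d)
      dS_d <- gd$dstream + gt$dother
      dS_t <- gt$dstream + gd$dother
    } else {
      gd <- bwd_mca_stack(dZ_dt, params$dec_drug$mca, cc$mca_d$caches,
                          cc$L_ds, B, d)
      gt <- bwd_mca_stack(dZ_td, params$dec_tgt$mca, cc$mca_t$caches,
                          cc$L_ts, B, d)
      dS_t <- gd$dstream + gt$dother
      dS_d <- gt$dstream + gd$dother
    }
    grads$dec_drug <- list(mca = gd$grads)
    grads$dec_tgt <- list(mca = gt$grads)
  } else {
    dS_d <- dZ_dt; dS_t <- dZ_td
    grads$dec_drug <- list(); grads$dec_tgt <- list()
  }
  gsd <- bwd_msa_stack(dS_d, params$dec_drug$msa, cc$sd)
  gst <- bwd_msa_stack(dS_t, params$dec_tgt$msa, cc$st)
  grads$dec_drug$msa <- gsd$grads
  grads$dec_tgt$msa <- gst$grads
  dX_drug <- gsd$dx; dX_tgt <- gst$dx
  if (cfg$task == "dti") {
    gt2 <- encode_target_bwd(dX_tgt, params, cfg, cc$cache_tgt, B)
    grads <- merge_grads(grads, gt2$grads)
  } else {
    gt2 <- encode_drug_bwd(dX_tgt, params, plans, cfg, cc$cache_tgt, B)
    grads <- merge_grads(grads, gt2$grads)
  }
  gd2 <- encode_drug_bwd(dX_drug, params, plans, cfg, cc$ed$cache, B)
  grads <- merge_grads(grads, gd2$grads)
  grads
}

# Recursively sum two gradient trees (missing entries treated as zero).
merge_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a) && is.list(b)) {
    keys <- union(names(a), names(b))
    if (is.null(names(a))) {  # positional lists (layer stacks)
      out <- vector("list", max(length(a), length(b)))
      for (i in seq_along(out))
        out[[i]] <- merge_grads(if (i <= length(a)) a[[i]] else NULL,
                                if (i <= length(b)) b[[i]] else NULL)
      return(out)
    }
    out <- stats::setNames(vector("list", length(keys)), keys)
    for (k in keys) out[[k]] <- merge_grads(a[[k]], b[[k]])
    return(out)
  }
  a + b
}
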