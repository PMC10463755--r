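# Batched neural-network primitives with explicit forward/backward passes.
#
# Token streams are stored as (B*L) x d matrices with example-major row
# order (example 1 rows first). Convolutional feature maps are stored as
# (B*H*W) x C matrices with rows ordered (example, row y, column x).
# Every *_fwd returns list(out, cache); the matching *_bwd consumes the
# upstream gradient and the cache and returns the input gradient plus
# parameter gradients.

LN_EPS <- 1e-5
BN_EPS <- 1e-5

init_glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

lin_fwd <- function(x, W, b) {
  out <- add_bias_inplace(x %*% W, b)
  list(out = out, cache = list(x = x, W = W))
}

lin_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

ln_fwd <- function(x, g, b) {
  r <- ln_fwd_cpp(x, g, b, LN_EPS)
  list(out = r$out, cache = list(xhat = r$xhat, inv = r$inv, g = g))
}

ln_bwd <- function(dout, cache) {
  r <- ln_bwd_cpp(dout, cache$xhat, cache$inv, cache$g)
  list(dx = r$dx, dg = as.vector(r$dg), db = as.vector(r$db))
}

relu_fwd <- function(x) {
  r <- relu_fwd_cpp(x)
  list(out = r$out, cache = r$mask)
}

relu_bwd <- function(dout, cache) dout * cache

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# idx: B x L integer matrix of 0-based token indices; W: V x d.
emb_fwd <- function(idx, W) {
  flat <- as.vector(t(idx)) + 1L
  list(out = W[flat, , drop = FALSE], cache = list(flat = flat, V = nrow(W)))
}

emb_bwd <- function(dout, cache) {
  agg <- rowsum(dout, group = cache$flat)
  dW <- matrix(0, cache$V, ncol(dout))
  dW[as.integer(rownames(agg)), ] <- agg
  list(dW = dW)
}

# Multi-head attention core over a batch. Xq: (B*Lq) x d, Xkv: (B*Lk) x d,
# mask: B x Lk logical (TRUE = valid key). p: Wq,bq,Wk,bk,Wv,bv,Wo,bo.
mha_fwd <- function(Xq, Xkv, p, H, mask, B, Lq, Lk, self = FALSE) {
  d <- ncol(Xq); dh <- d %/% H
  if (self) {
    qkv <- add_bias_inplace(Xq %*% cbind(p$Wq, p$Wk, p$Wv),
                            c(p$bq, p$bk, p$bv))
    Q <- qkv[, 1:d, drop = FALSE]
    K <- qkv[, (d + 1L):(2L * d), drop = FALSE]
    V <- qkv[, (2L * d + 1L):(3L * d), drop = FALSE]
  } else {
    Q <- add_bias_inplace(Xq %*% p$Wq, p$bq)
    kv <- add_bias_inplace(Xkv %*% cbind(p$Wk, p$Wv), c(p$bk, p$bv))
    K <- kv[, 1:d, drop = FALSE]
    V <- kv[, (d + 1L):(2L * d), drop = FALSE]
  }
  core <- mha_core_fwd_cpp(Q, K, V, matrix(as.integer(mask), nrow(mask)),
                           H, B, Lq, Lk)
  o <- lin_fwd(core$ctx, p$Wo, p$bo)
  A <- core$A
  dim(A) <- c(Lq, Lk, H, B)
  list(out = o$out,
       cache = list(Xq = Xq, Xkv = Xkv, o = o$cache, self = self, p = p,
                    Q = Q, K = K, V = V, A = A,
                    H = H, B = B, Lq = Lq, Lk = Lk, dh = dh))
}

mha_bwd <- function(dout, cache) {
  H <- cache$H; B <- cache$B; Lq <- cache$Lq; Lk <- cache$Lk
  p <- cache$p; d <- ncol(cache$Q)
  go <- lin_bwd(dout, cache$o)
  A <- cache$A
  dim(A) <- c(Lq, Lk, H * B)
  core <- mha_core_bwd_cpp(go$dx, cache$Q, cache$K, cache$V, A,
                           H, B, Lq, Lk)
  if (cache$self) {
    dqkv <- cbind(core$dQ, core$dK, core$dV)
    dXq <- dqkv %*% t(cbind(p$Wq, p$Wk, p$Wv))
    dW <- crossprod(cache$Xq, dqkv)
    db <- colSums(dqkv)
    dXkv <- matrix(0, nrow(dXq), d)
  } else {
    dXq <- core$dQ %*% t(p$Wq)
    dkv <- cbind(core$dK, core$dV)
    dXkv <- dkv %*% t(cbind(p$Wk, p$Wv))
    dWq <- crossprod(cache$Xq, core$dQ)
    dWkv <- crossprod(cache$Xkv, dkv)
    dW <- cbind(dWq, dWkv)
    db <- c(colSums(core$dQ), colSums(dkv))
  }
  list(dXq = dXq, dXkv = dXkv,
       grads = list(Wq = dW[, 1:d, drop = FALSE], bq = db[1:d],
                    Wk = dW[, (d + 1L):(2L * d), drop = FALSE],
                    bk = db[(d + 1L):(2L * d)],
                    Wv = dW[, (2L * d + 1L):(3L * d), drop = FALSE],
                    bv = db[(2L * d + 1L):(3L * d)],
                    Wo = go$dW, bo = go$db))
}

init_attn_params <- function(d) {
  list(Wq = init_glorot(d, d), bq = rep(0, d),
       Wk = init_glorot(d, d), bk = rep(0, d),
       Wv = init_glorot(d, d), bv = rep(0, d),
       Wo = init_glorot(d, d), bo = rep(0, d))
}

init_mlp_params <- function(d, hidden) {
  list(W1 = init_glorot(d, hidden), b1 = rep(0, hidden),
       W2 = init_glorot(hidden, d), b2 = rep(0, d))
}

mlp_fwd <- function(x, p) {
  l1 <- lin_fwd(x, p$W1, p$b1)
  r <- relu_fwd(l1$out)
  l2 <- lin_fwd(r$out, p$W2, p$b2)
  list(out = l2$out, cache = list(l1 = l1$cache, r = r$cache, l2 = l2$cache))
}

mlp_bwd <- function(dout, cache) {
  g2 <- lin_bwd(dout, cache$l2)
  dr <- relu_bwd(g2$dx, cache$r)
  g1 <- lin_bwd(dr, cache$l1)
  list(dx = g1$dx,
       grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db))
}

# One pre-norm self-attention layer: x + Drop(MHA(LN(x))) then
# + Drop(MLP(LN(.))). p: ln1_g, ln1_b, attn, ln2_g, ln2_b, mlp.
msa_layer_fwd <- function(x, p, H, mask, B, L, rate = 0, train = FALSE) {
  n1 <- ln_fwd(x, p$ln1_g, p$ln1_b)
  at <- mha_fwd(n1$out, n1$out, p$attn, H, mask, B, L, L, self = TRUE)
  d1 <- dropout_fwd(at$out, rate, train)
  x1 <- x + d1$out
  n2 <- ln_fwd(x1, p$ln2_g, p$ln2_b)
  ml <- mlp_fwd(n2$out, p$mlp)
  d2 <- dropout_fwd(ml$out, rate, train)
  out <- x1 + d2$out
  list(out = out, cache = list(n1 = n1$cache, at = at$cache, d1 = d1$cache,
                               n2 = n2$cache, ml = ml$cache, d2 = d2$cache),
       attn = at$cache$A)
}

msa_layer_bwd <- function(dout, cache) {
  dml <- dropout_bwd(dout, cache$d2)
  gm <- mlp_bwd(dml, cache$ml)
  gn2 <- ln_bwd(gm$dx, cache$n2)
  dx1 <- dout + gn2$dx
  dat <- dropout_bwd(dx1, cache$d1)
  ga <- mha_bwd(dat, cache$at)
  gn1 <- ln_bwd(ga$dXq + ga$dXkv, cache$n1)
  list(dx = dx1 + gn1$dx,
       grads = list(ln1_g = gn1$dg, ln1_b = gn1$db, attn = ga$grads,
                    ln2_g = gn2$dg, ln2_b = gn2$db, mlp = gm$grads))
}

# One pre-norm cross-attention layer. Queries from `stream`, keys/values
# from `other` (or flipped upstream by the caller). p adds lnkv_g, lnkv_b.
mca_layer_fwd <- function(stream, other, p, H, mask_other, B, Ls, Lo,
                          rate = 0, train = FALSE) {
  n1 <- ln_fwd(stream, p$ln1_g, p$ln1_b)
  nk <- ln_fwd(other, p$lnkv_g, p$lnkv_b)
  at <- mha_fwd(n1$out, nk$out, p$attn, H, mask_other, B, Ls, Lo)
  d1 <- dropout_fwd(at$out, rate, train)
  x1 <- stream + d1$out
  n2 <- ln_fwd(x1, p$ln2_g, p$ln2_b)
  ml <- mlp_fwd(n2$out, p$mlp)
  d2 <- dropout_fwd(ml$out, rate, train)
  out <- x1 + d2$out
  list(out = out, cache = list(n1 = n1$cache, nk = nk$cache, at = at$cache,
                               d1 = d1$cache, n2 = n2$cache, ml = ml$cache,
                               d2 = d2$cache),
       attn = at$cache$A)
}

mca_layer_bwd <- function(dout, cache) {
  dml <- dropout_bwd(dout, cache$d2)
  gm <- mlp_bwd(dml, cache$ml)
  gn2 <- ln_bwd(gm$dx, cache$n2)
  dx1 <- dout + gn2$dx
  dat <- dropout_bwd(dx1, cache$d1)
  ga <- mha_bwd(dat, cache$at)
  gn1 <- ln_bwd(ga$dXq, cache$n1)
  gnk <- ln_bwd(ga$dXkv, cache$nk)
  list(dstream = dx1 + gn1$dx, dother = gnk$dx,
       grads = list(ln1_g = gn1$dg, ln1_b = gn1$db,
                    lnkv_g = gnk$dg, lnkv_b = gnk$db, attn = ga$grads,
                    ln2_g = gn2$dg, ln2_b = gn2$db, mlp = gm$grads))
}

init_msa_layer <- function(d, mlp_ratio) {
  list(ln1_g = rep(1, d), ln1_b = rep(0, d), attn = init_attn_params(d),
       ln2_g = rep(1, d), ln2_b = rep(0, d),
       mlp = init_mlp_params(d, max(1L, round(mlp_ratio * d))))
}

init_mca_layer <- function(d, mlp_ratio) {
  p <- init_msa_layer(d, mlp_ratio)
  p$lnkv_g <- rep(1, d); p$lnkv_b <- rep(0, d)
  p
}

# ---- convolution machinery ------------------------------------------------

# im2col gather plan for a kh x kw convolution with same-size zero padding.
# Per kernel offset, the within-image source index of each output pixel
# (0 where the offset falls outside). Batch gather indices are cached per
# batch size in the plan's environment.
conv_plan <- function(H, W, kh = 3L, kw = 3L) {
  pos <- expand.grid(x = seq_len(W), y = seq_len(H))  # x fastest: (y,x) rows
  offs <- expand.grid(dx = seq_len(kw) - (kw %/% 2L + 1L),
                      dy = seq_len(kh) - (kh %/% 2L + 1L))
  idx <- matrix(0L, H * W, kh * kw)
  for (o in seq_len(nrow(offs))) {
    yy <- pos$y + offs$dy[o]; xx <- pos$x + offs$dx[o]
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    idx[ok, o] <- (yy[ok] - 1L) * W + xx[ok]
  }
  list(idx = idx, H = H, W = W, K = kh * kw)
}

# x: (B*H*W) x Cin -> (B*H*W) x (K*Cin) patch matrix (channel fastest
# within each kernel offset).
im2col <- function(x, plan, B) {
  list(cols = conv_im2col_cpp(x, plan$idx, B), plan = plan, B = B,
       Cin = ncol(x))
}

col2im <- function(dcols, meta) {
  conv_col2im_cpp(dcols, meta$plan$idx, meta$B, meta$Cin)
}

conv_fwd <- function(x, W, b, plan, B) {
  ic <- im2col(x, plan, B)
  l <- lin_fwd(ic$cols, W, b)
  list(out = l$out, cache = list(ic = ic, lin = l$cache))
}

conv_bwd <- function(dout, cache) {
  g <- lin_bwd(dout, cache$lin)
  list(dx = col2im(g$dx, cache$ic), dW = g$dW, db = g$db)
}

bn_fwd <- function(x, g, b, run_mu, run_var, train, momentum = 0.1) {
  n <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
    run_mu <- (1 - momentum) * run_mu + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mu; v <- run_var
    xc <- x - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(inv, each = n)
  out <- xhat * rep(g, each = n) + rep(b, each = n)
  list(out = out, run_mu = run_mu, run_var = run_var,
       cache = list(xhat = xhat, inv = inv, g = g, train = train))
}

bn_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  n <- nrow(dout)
  dg <- colSums(dout * xhat); db <- colSums(dout)
  dxhat <- dout * rep(cache$g, each = n)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) *
      rep(cache$inv, each = n)
  } else {
    dx <- dxhat * rep(cache$inv, each = n)
  }
  list(dx = dx, dg = dg, db = db)
}

# 2x2 max-pool plan: for each output pixel the 4 source positions.
pool_plan <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  pos <- expand.grid(x = seq_len(Wo), y = seq_len(Ho))
  src <- function(dy, dx) (2L * (pos$y - 1L) + dy - 1L) * W + 2L * (pos$x - 1L) + dx
  list(idx = cbind(src(1L, 1L), src(1L, 2L), src(2L, 1L), src(2L, 2L)),
       H = H, W = W, Ho = Ho, Wo = Wo)
}

pool_fwd <- function(x, plan, B) {
  P <- plan$H * plan$W
  r <- pool_fwd_cpp(x, plan$idx, B, P)
  list(out = r$out, cache = list(arg = r$arg, plan = plan, B = B, P = P))
}

pool_bwd <- function(dout, cache) {
  pool_bwd_cpp(dout, cache$arg, cache$plan$idx, cache$B, cache$P)
}

# ---- token-axis adaptive resampling ---------------------------------------

#' Adaptive token-axis resampling matrix
#'
#' Builds the `L_out x L_in` averaging matrix of adaptive average pooling:
#' output bin `i` averages input positions `floor((i-1)*L_in/L_out)+1` to
#' `ceiling(i*L_in/L_out)`. Works for both down- and up-sampling; rows sum
#' to 1.
#'
#' @param L_in,L_out Input/output token counts.
#' @return An `L_out x L_in` matrix.
#' @export
resample_matrix <- function(L_in, L_out) {
  A <- matrix(0, L_out, L_in)
  for (i in seq_len(L_out)) {
    s <- floor((i - 1) * L_in / L_out) + 1L
    e <- ceiling(i * L_in / L_out)
    A[i, s:e] <- 1 / (e - s + 1L)
  }
  A
}

# Apply the resampling matrix per example across a batch.
resample_fwd <- function(x, A, B, L_in) {
  L_out <- nrow(A)
  out <- matrix(0, B * L_out, ncol(x))
  for (b in seq_len(B)) {
    out[((b - 1L) * L_out + 1L):(b * L_out), ] <-
      A %*% x[((b - 1L) * L_in + 1L):(b * L_in), , drop = FALSE]
  }
  out
}

resample_bwd <- function(dout, A, B, L_in) {
  L_out <- nrow(A)
  dx <- matrix(0, B * L_in, ncol(dout))
  tA <- t(A)
  for (b in seq_len(B)) {
    dx[((b - 1L) * L_in + 1L):(b * L_in), ] <-
      tA %*% dout[((b - 1L) * L_out + 1L):(b * L_out), , drop = FALSE]
  }
  dx
}
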