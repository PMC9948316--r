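# Transformer encoder-decoder in base R (BLAS matrix ops) with manual
# backpropagation. Pre-layer-norm sublayers with final norms after both
# stacks, sinusoidal positional encoding on both sides, ReLU feed-forward,
# untied embeddings scaled by sqrt(d_model). Parameters live in one flat
# named list of matrices/vectors, which keeps the Adam update and the
# finite-difference checks simple.

PAD_IDX <- 1L; BOS_IDX <- 2L; EOS_IDX <- 3L; UNK_IDX <- 4L

#' Transformer model configuration
#'
#' Defaults mirror the reference architecture for this task: 6 layers,
#' 8 heads, 512-dimensional attention, 2048-dimensional feed-forward,
#' dropout 0.1, pre-layer-norm, sinusoidal positional encoding.
#'
#' @param n_layers encoder and decoder depth.
#' @param n_heads attention heads; must divide \code{d_model}.
#' @param d_model embedding/attention width.
#' @param d_ff feed-forward inner width.
#' @param dropout dropout rate in [0,1).
#' @param pre_layer_norm normalize before each sublayer (fixed design).
#' @param positional_encoding add sinusoidal position information.
#' @param max_len_src,max_len_tgt hard sequence-length caps.
#' @param src_vocab_size,tgt_vocab_size vocabulary sizes (with specials).
#' @return object of class \code{model_config}.
#' @export
model_config <- function(n_layers = 6L, n_heads = 8L, d_model = 512L,
                         d_ff = 2048L, dropout = 0.1,
                         pre_layer_norm = TRUE, positional_encoding = TRUE,
                         max_len_src = 512L, max_len_tgt = 256L,
                         src_vocab_size = NULL, tgt_vocab_size = NULL) {
  stopifnot(d_model %% n_heads == 0, dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 dropout = dropout, pre_layer_norm = isTRUE(pre_layer_norm),
                 positional_encoding = isTRUE(positional_encoding),
                 max_len_src = as.integer(max_len_src),
                 max_len_tgt = as.integer(max_len_tgt),
                 src_vocab_size = src_vocab_size,
                 tgt_vocab_size = tgt_vocab_size),
            class = "model_config")
}

# sinusoidal positional encoding table (max_len x d)
sinusoidal_pe <- function(max_len, d) {
  pos <- seq_len(max_len) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 10000^(-(i %/% 2 * 2) / d))
  pe <- matrix(0, max_len, d)
  even <- which(i %% 2 == 0); odd <- which(i %% 2 == 1)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

xavier <- function(n_in, n_out) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out)
}

#' Initialize a transformer model
#'
#' @param cfg a \code{\link{model_config}} with vocabulary sizes set.
#' @param seed RNG seed for weight initialization.
#' @return list of class \code{transformer} with \code{params} (flat named
#'   list), \code{cfg} and the positional-encoding tables.
#' @export
init_transformer <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"),
            !is.null(cfg$src_vocab_size), !is.null(cfg$tgt_vocab_size))
  set.seed(seed)
  d <- cfg$d_model; dff <- cfg$d_ff
  p <- list(
    src_emb = matrix(stats::rnorm(cfg$src_vocab_size * d, 0, 1 / sqrt(d)),
                     cfg$src_vocab_size, d),
    tgt_emb = matrix(stats::rnorm(cfg$tgt_vocab_size * d, 0, 1 / sqrt(d)),
                     cfg$tgt_vocab_size, d)
  )
  sub <- function(prefix, cross = FALSE) {
    out <- list()
    out[[paste0(prefix, ".ln1.g")]] <- rep(1, d)
    out[[paste0(prefix, ".ln1.b")]] <- rep(0, d)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      out[[paste0(prefix, ".self.", w)]] <- xavier(d, d)
    }
    if (cross) {
      out[[paste0(prefix, ".ln2.g")]] <- rep(1, d)
      out[[paste0(prefix, ".ln2.b")]] <- rep(0, d)
      for (w in c("Wq", "Wk", "Wv", "Wo")) {
        out[[paste0(prefix, ".cross.", w)]] <- xavier(d, d)
      }
    }
    lnf <- if (cross) "ln3" else "ln2"
    out[[paste0(prefix, ".", lnf, ".g")]] <- rep(1, d)
    out[[paste0(prefix, ".", lnf, ".b")]] <- rep(0, d)
    out[[paste0(prefix, ".ff.W1")]] <- xavier(d, dff)
    out[[paste0(prefix, ".ff.b1")]] <- rep(0, dff)
    out[[paste0(prefix, ".ff.W2")]] <- xavier(dff, d)
    out[[paste0(prefix, ".ff.b2")]] <- rep(0, d)
    out
  }
  for (l in seq_len(cfg$n_layers)) p <- c(p, sub(sprintf("enc%d", l)))
  p[["enc_ln.g"]] <- rep(1, d); p[["enc_ln.b"]] <- rep(0, d)
  for (l in seq_len(cfg$n_layers)) p <- c(p, sub(sprintf("dec%d", l), cross = TRUE))
  p[["dec_ln.g"]] <- rep(1, d); p[["dec_ln.b"]] <- rep(0, d)
  p[["out.W"]] <- xavier(d, cfg$tgt_vocab_size)
  p[["out.b"]] <- rep(0, cfg$tgt_vocab_size)
  structure(list(params = p, cfg = cfg,
                 pe_src = sinusoidal_pe(cfg$max_len_src, d),
                 pe_tgt = sinusoidal_pe(cfg$max_len_tgt, d)),
            class = "transformer")
}

#' Count trainable parameters
#'
#' @param model a \code{transformer} or a \code{model_config} (with
#'   vocabulary sizes).
#' @return integer total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "model_config")) model <- init_transformer(model, seed = 0L)
  sum(vapply(model$params, length, integer(1)))
}

# --- primitive fwd/bwd -----------------------------------------------------

ln_fwd <- function(X, g, b, eps = 1e-5) ln_fwd_cpp(X, g, b, eps)

ln_bwd <- function(dY, cache, g) ln_bwd_cpp(dY, cache$xhat, cache$sd, g)

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# add a row vector to every row without sweep()'s aperm overhead
add_rowvec <- function(X, b) X + rep(b, each = nrow(X))

# dropout with inverted scaling; returns NULL mask in eval mode
drop_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

drop_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# multi-head attention over contiguous equal-length row blocks
# (sequence-major layout); the batched per-head core runs in C++.
# key_valid: list per sequence of logical vectors (valid keys).
mha_fwd <- function(Xq, Xkv, Wq, Wk, Wv, Wo, n_heads, blocks_q, blocks_kv,
                    key_valid, causal = FALSE, capture = FALSE) {
  B <- length(blocks_q)
  Lq <- length(blocks_q[[1]]); Lk <- length(blocks_kv[[1]])
  Q <- Xq %*% Wq; K <- Xkv %*% Wk; V <- Xkv %*% Wv
  kvmat <- matrix(as.integer(unlist(key_valid)), B, Lk, byrow = TRUE)
  core <- mha_core_fwd(Q, K, V, B, Lq, Lk, n_heads, kvmat, causal)
  attn <- NULL
  if (capture) {
    attn <- lapply(seq_len(B), function(s) {
      lapply(seq_len(n_heads), function(h)
        t(matrix(core$P[, , (s - 1L) * n_heads + h], Lk, Lq)))
    })
  }
  list(Y = core$O %*% Wo,
       cache = list(Q = Q, K = K, V = V, O = core$O, P = core$P,
                    Xq = Xq, Xkv = Xkv, B = B, Lq = Lq, Lk = Lk),
       attn = attn)
}

mha_bwd <- function(dY, cache, Wq, Wk, Wv, Wo, n_heads, blocks_q, blocks_kv) {
  dWo <- crossprod(cache$O, dY)
  dO <- tcrossprod(dY, Wo)
  core <- mha_core_bwd(dO, cache$Q, cache$K, cache$V, cache$P,
                       cache$B, cache$Lq, cache$Lk, n_heads)
  list(dXq = tcrossprod(core$dQ, Wq),
       dXkv = tcrossprod(core$dK, Wk) + tcrossprod(core$dV, Wv),
       dWq = crossprod(cache$Xq, core$dQ),
       dWk = crossprod(cache$Xkv, core$dK),
       dWv = crossprod(cache$Xkv, core$dV), dWo = dWo)
}

# --- full forward ----------------------------------------------------------

# batch: list(src: B x Ls integer matrix (PAD-right), tgt_in, tgt_out:
# B x Lt integer matrices). Rows of the flattened representation are
# sequence-major: row (b-1)*L + t.
transformer_forward <- function(model, batch, train = FALSE,
                                need_cache = FALSE, capture_attention = FALSE,
                                src_embed_override = NULL) {
  p <- model$params; cfg <- model$cfg
  d <- cfg$d_model; H <- cfg$n_heads; drp <- cfg$dropout
  src <- batch$src; tgt_in <- batch$tgt_in
  B <- nrow(src); Ls <- ncol(src); Lt <- ncol(tgt_in)
  stopifnot(Ls <= cfg$max_len_src, Lt <= cfg$max_len_tgt)
  if (max(src) > cfg$src_vocab_size || max(tgt_in) > cfg$tgt_vocab_size) {
    stop("token index outside vocabulary range")
  }
  blocks_s <- lapply(seq_len(B), function(b) ((b - 1L) * Ls + 1L):(b * Ls))
  blocks_t <- lapply(seq_len(B), function(b) ((b - 1L) * Lt + 1L):(b * Lt))
  src_valid <- lapply(seq_len(B), function(b) src[b, ] != PAD_IDX)
  tgt_valid <- lapply(seq_len(B), function(b) tgt_in[b, ] != PAD_IDX)
  src_idx <- as.vector(t(src)); tgt_idx <- as.vector(t(tgt_in))
  X0 <- if (is.null(src_embed_override)) {
    p$src_emb[src_idx, , drop = FALSE] * sqrt(d)
  } else src_embed_override
  if (cfg$positional_encoding) {
    X0 <- X0 + model$pe_src[rep(seq_len(Ls), B), , drop = FALSE]
  }
  cache <- if (need_cache) list() else NULL
  dr <- drop_fwd(X0, drp, train)
  if (need_cache) cache$src_drop <- dr$mask
  X <- dr$Y
  for (l in seq_len(cfg$n_layers)) {
    pf <- sprintf("enc%d", l)
    c_l <- list()
    ln1 <- ln_fwd(X, p[[paste0(pf, ".ln1.g")]], p[[paste0(pf, ".ln1.b")]])
    at <- mha_fwd(ln1$Y, ln1$Y, p[[paste0(pf, ".self.Wq")]],
                  p[[paste0(pf, ".self.Wk")]], p[[paste0(pf, ".self.Wv")]],
                  p[[paste0(pf, ".self.Wo")]], H, blocks_s, blocks_s,
                  src_valid, causal = FALSE)
    d1 <- drop_fwd(at$Y, drp, train)
    X <- X + d1$Y
    ln2 <- ln_fwd(X, p[[paste0(pf, ".ln2.g")]], p[[paste0(pf, ".ln2.b")]])
    pre <- add_rowvec(ln2$Y %*% p[[paste0(pf, ".ff.W1")]],
                      p[[paste0(pf, ".ff.b1")]])
    hidden <- pre * (pre > 0)
    ff <- add_rowvec(hidden %*% p[[paste0(pf, ".ff.W2")]],
                     p[[paste0(pf, ".ff.b2")]])
    d2 <- drop_fwd(ff, drp, train)
    X <- X + d2$Y
    if (need_cache) {
      c_l$ln1 <- ln1; c_l$at <- at$cache; c_l$d1 <- d1$mask
      c_l$ln2 <- ln2; c_l$pre <- pre; c_l$hidden <- hidden; c_l$d2 <- d2$mask
      cache[[pf]] <- c_l
    }
  }
  lne <- ln_fwd(X, p[["enc_ln.g"]], p[["enc_ln.b"]])
  enc_out <- lne$Y
  if (need_cache) { cache$enc_last <- X; cache$enc_ln <- lne }

  Y0 <- p$tgt_emb[tgt_idx, , drop = FALSE] * sqrt(d)
  if (cfg$positional_encoding) {
    Y0 <- Y0 + model$pe_tgt[rep(seq_len(Lt), B), , drop = FALSE]
  }
  drt <- drop_fwd(Y0, drp, train)
  if (need_cache) cache$tgt_drop <- drt$mask
  Y <- drt$Y
  attn_maps <- if (capture_attention) list() else NULL
  for (l in seq_len(cfg$n_layers)) {
    pf <- sprintf("dec%d", l)
    ln1 <- ln_fwd(Y, p[[paste0(pf, ".ln1.g")]], p[[paste0(pf, ".ln1.b")]])
    at1 <- mha_fwd(ln1$Y, ln1$Y, p[[paste0(pf, ".self.Wq")]],
                   p[[paste0(pf, ".self.Wk")]], p[[paste0(pf, ".self.Wv")]],
                   p[[paste0(pf, ".self.Wo")]], H, blocks_t, blocks_t,
                   tgt_valid, causal = TRUE)
    d1 <- drop_fwd(at1$Y, drp, train)
    Y <- Y + d1$Y
    ln2 <- ln_fwd(Y, p[[paste0(pf, ".ln2.g")]], p[[paste0(pf, ".ln2.b")]])
    at2 <- mha_fwd(ln2$Y, enc_out, p[[paste0(pf, ".cross.Wq")]],
                   p[[paste0(pf, ".cross.Wk")]], p[[paste0(pf, ".cross.Wv")]],
                   p[[paste0(pf, ".cross.Wo")]], H, blocks_t, blocks_s,
                   src_valid, causal = FALSE, capture = capture_attention)
    if (capture_attention) attn_maps[[l]] <- at2$attn
    d2 <- drop_fwd(at2$Y, drp, train)
    Y <- Y + d2$Y
    ln3 <- ln_fwd(Y, p[[paste0(pf, ".ln3.g")]], p[[paste0(pf, ".ln3.b")]])
    pre <- add_rowvec(ln3$Y %*% p[[paste0(pf, ".ff.W1")]],
                      p[[paste0(pf, ".ff.b1")]])
    hidden <- pre * (pre > 0)
    ff <- add_rowvec(hidden %*% p[[paste0(pf, ".ff.W2")]],
                     p[[paste0(pf, ".ff.b2")]])
    d3 <- drop_fwd(ff, drp, train)
    Y <- Y + d3$Y
    if (need_cache) {
      cache[[pf]] <- list(
        ln1 = ln1, at1 = at1$cache, d1 = d1$mask,
        ln2 = ln2, at2 = at2$cache, d2 = d2$mask,
        ln3 = ln3, pre = pre, hidden = hidden, d3 = d3$mask
      )
    }
  }
  lnd <- ln_fwd(Y, p[["dec_ln.g"]], p[["dec_ln.b"]])
  logits <- add_rowvec(lnd$Y %*% p[["out.W"]], p[["out.b"]])
  m <- logits[cbind(seq_len(nrow(logits)),
                    max.col(logits, ties.method = "first"))]
  lse <- m + log(rowSums(exp(logits - m)))
  logp <- logits - lse
  loss <- NA_real_
  if (!is.null(batch$tgt_out)) {
    out_idx <- as.vector(t(batch$tgt_out))
    valid <- out_idx != PAD_IDX
    picked <- logp[cbind(seq_along(out_idx), out_idx)]
    loss <- -sum(picked[valid]) / sum(valid)
  }
  if (need_cache) {
    cache$dec_last <- Y; cache$dec_ln <- lnd; cache$logp <- logp
    cache$blocks_s <- blocks_s; cache$blocks_t <- blocks_t
    cache$src_valid <- src_valid; cache$tgt_valid <- tgt_valid
    cache$src_idx <- src_idx; cache$tgt_idx <- tgt_idx
    cache$enc_out <- enc_out
  }
  list(logp = logp, loss = loss, cache = cache, attn = attn_maps,
       enc_out = enc_out)
}

# --- full backward ---------------------------------------------------------

# dlogp_seed: optional (B*Lt) x V matrix of gradients w.r.t. log-probs;
# defaults to the mean-NLL seed over non-pad target positions.
transformer_backward <- function(model, batch, fwd, dlogp_seed = NULL) {
  p <- model$params; cfg <- model$cfg
  d <- cfg$d_model; H <- cfg$n_heads
  cache <- fwd$cache
  stopifnot(!is.null(cache))
  logp <- cache$logp
  N_t <- nrow(logp)
  if (is.null(dlogp_seed)) {
    out_idx <- as.vector(t(batch$tgt_out))
    valid <- out_idx != PAD_IDX
    nv <- sum(valid)
    dlogp_seed <- matrix(0, N_t, ncol(logp))
    dlogp_seed[cbind(which(valid), out_idx[valid])] <- -1 / nv
  }
  # logp = logits - lse: dlogits = dlogp - softmax * rowSums(dlogp)
  probs <- exp(logp)
  dlogits <- dlogp_seed - probs * rowSums(dlogp_seed)
  grads <- list()
  gadd <- function(name, val) {
    grads[[name]] <<- if (is.null(grads[[name]])) val else grads[[name]] + val
  }
  lnd <- cache$dec_ln
  gadd("out.W", crossprod(lnd$Y, dlogits))
  gadd("out.b", colSums(dlogits))
  dlnY <- tcrossprod(dlogits, p[["out.W"]])
  lb <- ln_bwd(dlnY, lnd, p[["dec_ln.g"]])
  gadd("dec_ln.g", lb$dg); gadd("dec_ln.b", lb$db)
  dY <- lb$dX
  d_enc_out <- matrix(0, nrow(cache$enc_out), d)
  for (l in rev(seq_len(cfg$n_layers))) {
    pf <- sprintf("dec%d", l)
    cl <- cache[[pf]]
    # FFN sublayer
    dff <- drop_bwd(dY, cl$d3)
    gadd(paste0(pf, ".ff.b2"), colSums(dff))
    gadd(paste0(pf, ".ff.W2"), crossprod(cl$hidden, dff))
    dh <- tcrossprod(dff, p[[paste0(pf, ".ff.W2")]])
    dpre <- dh * (cl$pre > 0)
    gadd(paste0(pf, ".ff.b1"), colSums(dpre))
    gadd(paste0(pf, ".ff.W1"), crossprod(cl$ln3$Y, dpre))
    dln3Y <- tcrossprod(dpre, p[[paste0(pf, ".ff.W1")]])
    lb <- ln_bwd(dln3Y, cl$ln3, p[[paste0(pf, ".ln3.g")]])
    gadd(paste0(pf, ".ln3.g"), lb$dg); gadd(paste0(pf, ".ln3.b"), lb$db)
    dY <- dY + lb$dX
    # cross-attention sublayer
    dat2 <- drop_bwd(dY, cl$d2)
    mb <- mha_bwd(dat2, cl$at2, p[[paste0(pf, ".cross.Wq")]],
                  p[[paste0(pf, ".cross.Wk")]], p[[paste0(pf, ".cross.Wv")]],
                  p[[paste0(pf, ".cross.Wo")]], H,
                  cache$blocks_t, cache$blocks_s)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      gadd(paste0(pf, ".cross.", w), mb[[paste0("d", w)]])
    }
    d_enc_out <- d_enc_out + mb$dXkv
    lb <- ln_bwd(mb$dXq, cl$ln2, p[[paste0(pf, ".ln2.g")]])
    gadd(paste0(pf, ".ln2.g"), lb$dg); gadd(paste0(pf, ".ln2.b"), lb$db)
    dY <- dY + lb$dX
    # masked self-attention sublayer
    dat1 <- drop_bwd(dY, cl$d1)
    mb <- mha_bwd(dat1, cl$at1, p[[paste0(pf, ".self.Wq")]],
                  p[[paste0(pf, ".self.Wk")]], p[[paste0(pf, ".self.Wv")]],
                  p[[paste0(pf, ".self.Wo")]], H,
                  cache$blocks_t, cache$blocks_t)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      gadd(paste0(pf, ".self.", w), mb[[paste0("d", w)]])
    }
    lb <- ln_bwd(mb$dXq + mb$dXkv, cl$ln1, p[[paste0(pf, ".ln1.g")]])
    gadd(paste0(pf, ".ln1.g"), lb$dg); gadd(paste0(pf, ".ln1.b"), lb$db)
    dY <- dY + lb$dX
  }
  dY0 <- drop_bwd(dY, cache$tgt_drop)
  gt <- rowsum(dY0 * sqrt(d), cache$tgt_idx)
  gte <- matrix(0, cfg$tgt_vocab_size, d)
  gte[as.integer(rownames(gt)), ] <- gt
  gadd("tgt_emb", gte)
  # encoder backward
  lb <- ln_bwd(d_enc_out, cache$enc_ln, p[["enc_ln.g"]])
  gadd("enc_ln.g", lb$dg); gadd("enc_ln.b", lb$db)
  dX <- lb$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    pf <- sprintf("enc%d", l)
    cl <- cache[[pf]]
    dff <- drop_bwd(dX, cl$d2)
    gadd(paste0(pf, ".ff.b2"), colSums(dff))
    gadd(paste0(pf, ".ff.W2"), crossprod(cl$hidden, dff))
    dh <- tcrossprod(dff, p[[paste0(pf, ".ff.W2")]])
    dpre <- dh * (cl$pre > 0)
    gadd(paste0(pf, ".ff.b1"), colSums(dpre))
    gadd(paste0(pf, ".ff.W1"), crossprod(cl$ln2$Y, dpre))
    dln2Y <- tcrossprod(dpre, p[[paste0(pf, ".ff.W1")]])
    lb <- ln_bwd(dln2Y, cl$ln2, p[[paste0(pf, ".ln2.g")]])
    gadd(paste0(pf, ".ln2.g"), lb$dg); gadd(paste0(pf, ".ln2.b"), lb$db)
    dX <- dX + lb$dX
    dat <- drop_bwd(dX, cl$d1)
    mb <- mha_bwd(dat, cl$at, p[[paste0(pf, ".self.Wq")]],
                  p[[paste0(pf, ".self.Wk")]], p[[paste0(pf, ".self.Wv")]],
                  p[[paste0(pf, ".self.Wo")]], H,
                  cache$blocks_s, cache$blocks_s)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      gadd(paste0(pf, ".self.", w), mb[[paste0("d", w)]])
    }
    lb <- ln_bwd(mb$dXq + mb$dXkv, cl$ln1, p[[paste0(pf, ".ln1.g")]])
    gadd(paste0(pf, ".ln1.g"), lb$dg); gadd(paste0(pf, ".ln1.b"), lb$db)
    dX <- dX + lb$dX
  }
  dX0 <- drop_bwd(dX, cache$src_drop)
  gs <- rowsum(dX0 * sqrt(d), cache$src_idx)
  gse <- matrix(0, cfg$src_vocab_size, d)
  gse[as.integer(rownames(gs)), ] <- gs
  gadd("src_emb", gse)
  list(grads = grads, d_src_embed = dX0)
}
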