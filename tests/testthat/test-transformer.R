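# Transformer forward/backward properties.

tiny_cfg <- function(pe = TRUE, dropout = 0) {
  model_config(n_layers = 2, n_heads = 2, d_model = 16, d_ff = 32,
               dropout = dropout, positional_encoding = pe,
               max_len_src = 16, max_len_tgt = 12,
               src_vocab_size = 12, tgt_vocab_size = 10)
}

tiny_batch <- function() {
  list(src = rbind(c(5L, 6L, 7L, 8L, 9L, 1L), c(6L, 6L, 8L, 1L, 1L, 1L)),
       tgt_in = rbind(c(2L, 5L, 6L, 7L, 1L), c(2L, 7L, 8L, 1L, 1L)),
       tgt_out = rbind(c(5L, 6L, 7L, 3L, 1L), c(7L, 8L, 3L, 1L, 1L)))
}

test_that("per-position probabilities and attention rows are normalized", {
  m <- init_transformer(tiny_cfg(), seed = 1)
  fwd <- fp2mol:::transformer_forward(m, tiny_batch(), capture_attention = TRUE)
  expect_lt(max(abs(rowSums(exp(fwd$logp)) - 1)), 1e-5)
  for (l in seq_along(fwd$attn)) {
    for (s in seq_along(fwd$attn[[l]])) {
      for (h in seq_along(fwd$attn[[l]][[s]])) {
        expect_lt(max(abs(rowSums(fwd$attn[[l]][[s]][[h]]) - 1)), 1e-6)
      }
    }
  }
})

test_that("evaluation-mode forward is bitwise stable", {
  m <- init_transformer(tiny_cfg(dropout = 0.1), seed = 2)
  f1 <- fp2mol:::transformer_forward(m, tiny_batch())
  f2 <- fp2mol:::transformer_forward(m, tiny_batch())
  expect_identical(f1$logp, f2$logp)
})

test_that("without positional encoding the encoder is order-invariant", {
  m <- init_transformer(tiny_cfg(pe = FALSE), seed = 3)
  ba <- tiny_batch()
  ba$src <- ba$src[1, , drop = FALSE][, 1:5, drop = FALSE]
  ba$tgt_in <- ba$tgt_in[1, , drop = FALSE]
  ba$tgt_out <- ba$tgt_out[1, , drop = FALSE]
  f1 <- fp2mol:::transformer_forward(m, ba)
  perm <- ba
  perm$src <- ba$src[, c(3, 1, 5, 2, 4), drop = FALSE]
  f2 <- fp2mol:::transformer_forward(m, perm)
  expect_equal(f1$logp, f2$logp, tolerance = 1e-10)
  # with positional encoding the permutation changes the output
  mp <- init_transformer(tiny_cfg(pe = TRUE), seed = 3)
  g1 <- fp2mol:::transformer_forward(mp, ba)
  g2 <- fp2mol:::transformer_forward(mp, perm)
  expect_gt(max(abs(g1$logp - g2$logp)), 1e-8)
})

test_that("analytic gradients match finite differences", {
  m <- init_transformer(tiny_cfg(), seed = 4)
  ba <- tiny_batch()
  fwd <- fp2mol:::transformer_forward(m, ba, need_cache = TRUE)
  bwd <- fp2mol:::transformer_backward(m, ba, fwd)
  eps <- 1e-6
  set.seed(11)
  for (nm in c("src_emb", "enc1.self.Wq", "dec2.cross.Wv", "dec1.ff.W1",
               "out.W", "enc_ln.g")) {
    i <- sample(length(m$params[[nm]]), 1)
    p0 <- m$params[[nm]][i]
    m$params[[nm]][i] <- p0 + eps
    lp <- fp2mol:::transformer_forward(m, ba)$loss
    m$params[[nm]][i] <- p0 - eps
    lm <- fp2mol:::transformer_forward(m, ba)$loss
    m$params[[nm]][i] <- p0
    fd <- (lp - lm) / (2 * eps)
    expect_equal(bwd$grads[[nm]][i], fd, tolerance = 1e-4)
  }
  # gradient w.r.t. source embeddings exists and is finite
  expect_true(all(is.finite(bwd$d_src_embed)))
})

test_that("parameter counts follow the layer algebra", {
  cfg <- tiny_cfg()
  d <- 16; dff <- 32; Vs <- 12; Vt <- 10
  enc_layer <- 4 * d * d + 2 * d + (d * dff + dff + dff * d + d) + 2 * d
  dec_layer <- enc_layer + 4 * d * d + 2 * d
  expected <- Vs * d + Vt * d +
    2 * enc_layer + 2 * d +
    2 * dec_layer + 2 * d +
    d * Vt + Vt
  expect_equal(count_parameters(cfg), expected)
  expect_identical(count_parameters(cfg), count_parameters(cfg))
  cfg3 <- tiny_cfg(); cfg3$n_layers <- 3L
  expect_gt(count_parameters(cfg3), count_parameters(cfg))
})

test_that("out-of-range indices are rejected", {
  m <- init_transformer(tiny_cfg(), seed = 5)
  ba <- tiny_batch()
  ba$src[1, 1] <- 99L
  expect_error(fp2mol:::transformer_forward(m, ba), "vocabulary")
})
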