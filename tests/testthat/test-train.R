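# Training engine: schedule shape, token-count batching, optimization.

test_that("the cyclic decayed schedule hits its printed endpoints", {
  cfg <- sched_config()   # peak 0.001, floor 3.9e-12, warmup 5000, cycle 25000
  expect_equal(lr_at(5000, cfg), 0.001)
  expect_equal(lr_at(25000, cfg), 3.9e-12)
  # halfway up the linear ramp
  expect_equal(lr_at(2500, cfg),
               3.9e-12 + (0.001 - 3.9e-12) * 2500 / 5000)
  expect_error(lr_at(0, cfg), "step")
})

test_that("the schedule is periodic and continuous at the junction", {
  cfg <- sched_config()
  s <- c(1, 17, 4999, 5000, 5001, 12345, 24999, 25000)
  expect_equal(lr_at(s, cfg), lr_at(s + 25000, cfg))
  expect_equal(lr_at(s, cfg), lr_at(s + 3 * 25000, cfg))
  # peak attained exactly at warmup; neighbors below it
  expect_lt(lr_at(4999, cfg), lr_at(5000, cfg))
  expect_lt(lr_at(5001, cfg), lr_at(5000, cfg))
  expect_true(all(lr_at(1:300 * 83, cfg) <= 0.001))
  # geometric decay: log-linear between warmup and cycle end
  mid <- exp((log(0.001) + log(3.9e-12)) / 2)
  expect_equal(lr_at(15000, cfg), mid, tolerance = 1e-9)
})

test_that("token-count batching respects its budget", {
  set.seed(20)
  pairs <- lapply(1:40, function(i) {
    ls <- sample(5:60, 1); lt <- sample(5:40, 1)
    list(src = sample(5:30, ls, TRUE), tgt = sample(5:30, lt, TRUE), id = i)
  })
  batches <- make_batches(pairs, tokens_per_batch = 300, seed = 1)
  expect_identical(sum(vapply(batches, function(b) nrow(b$src), integer(1))),
                   40L)
  for (b in batches) {
    foot <- (ncol(b$src) + ncol(b$tgt_in)) * nrow(b$src)
    expect_lte(foot, 300)
  }
  # ten identical 100-token pairs fit one 8000-token batch
  p10 <- lapply(1:10, function(i)
    list(src = rep(5L, 60), tgt = rep(6L, 39), id = i))
  expect_length(make_batches(p10, 8000, seed = 1), 1L)
  # a pair larger than the budget is an error naming the pair
  expect_error(make_batches(p10, 90, seed = 1), "exceeds")
})

test_that("training is deterministic and leaves zero-step runs untouched", {
  set.seed(33)
  mols <- fixture_tiny_fit_records()[1:8, ]
  v <- build_vocab(lapply(mols$smiles, tokenize_smiles))
  pairs <- lapply(seq_len(nrow(mols)), function(i) {
    toks <- encode_tokens(v, tokenize_smiles(mols$smiles[i]))
    list(src = toks, tgt = toks, id = mols$id[i])
  })
  cfg <- model_config(n_layers = 1, n_heads = 2, d_model = 16, d_ff = 32,
                      dropout = 0.1, max_len_src = 80, max_len_tgt = 80,
                      src_vocab_size = vocab_size(v),
                      tgt_vocab_size = vocab_size(v))
  m <- init_transformer(cfg, seed = 9)
  tc <- train_config(tokens_per_batch = 600, max_steps = 12,
                     checkpoint_every = 1000, seed = 10)
  sc <- sched_config(warmup_steps = 10, cycle_steps = 50)
  r1 <- train_translator(m, pairs, tc, sc)
  r2 <- train_translator(m, pairs, tc, sc)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$history$lr, lr_at(r1$history$step, sc))
  r0 <- train_translator(m, pairs, train_config(max_steps = 0), sc)
  expect_identical(r0$model$params, m$params)
  expect_identical(nrow(r0$history), 0L)
})

test_that("the loss ignores padding positions", {
  m <- init_transformer(model_config(n_layers = 1, n_heads = 2, d_model = 16,
                                     d_ff = 32, dropout = 0,
                                     max_len_src = 20, max_len_tgt = 20,
                                     src_vocab_size = 12, tgt_vocab_size = 12),
                        seed = 6)
  ba <- list(src = rbind(c(5L, 6L, 7L)), tgt_in = rbind(c(2L, 5L, 6L)),
             tgt_out = rbind(c(5L, 6L, 3L)))
  l1 <- fp2mol:::transformer_forward(m, ba)$loss
  pad <- function(x, k) cbind(x, matrix(1L, nrow(x), k))
  ba2 <- list(src = pad(ba$src, 3), tgt_in = pad(ba$tgt_in, 2),
              tgt_out = pad(ba$tgt_out, 2))
  l2 <- fp2mol:::transformer_forward(m, ba2)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("a one-pair corpus is memorized with decreasing loss", {
  v <- build_vocab(list(tokenize_smiles("CCOC(=O)C")))
  toks <- encode_tokens(v, tokenize_smiles("CCOC(=O)C"))
  pairs <- list(list(src = toks, tgt = toks, id = "p1"))
  cfg <- model_config(n_layers = 1, n_heads = 2, d_model = 16, d_ff = 32,
                      dropout = 0, max_len_src = 20, max_len_tgt = 20,
                      src_vocab_size = vocab_size(v),
                      tgt_vocab_size = vocab_size(v))
  m <- init_transformer(cfg, seed = 12)
  r <- train_translator(m, pairs, train_config(tokens_per_batch = 100,
                                               max_steps = 60, seed = 13),
                        sched_config(peak_lr = 0.01, warmup_steps = 10,
                                     cycle_steps = 80))
  # monotone decrease up to small tolerance, and large overall drop
  expect_lt(r$history$loss[60], r$history$loss[1] / 4)
  bumps <- diff(r$history$loss) > 0.05
  expect_lt(mean(bumps), 0.2)
})
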