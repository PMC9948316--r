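# Attribution: integrated gradients and attention maps.

test_that("integrated gradients satisfy completeness within 2% at 64 steps", {
  fit <- fixture_tiny_fit()
  mols <- fixture_tiny_fit_records()
  src <- featurize(mols$smiles[2], fit$spec)$tokens
  tgt <- tokenize_smiles(mols$smiles[2])
  ig <- integrated_gradients(fit$model, fit$src_vocab, fit$tgt_vocab,
                             src, tgt, m_steps = 64)
  expect_identical(dim(ig$scores), c(length(tgt), length(src)))
  expect_true(all(is.finite(ig$scores)))
  res <- abs(rowSums(ig$scores) - ig$completeness)
  denom <- pmax(abs(ig$completeness), 1)
  expect_lt(max(res / denom), 0.02)
  # coarser paths are less complete on the same instance
  ig4 <- integrated_gradients(fit$model, fit$src_vocab, fit$tgt_vocab,
                              src, tgt, m_steps = 4)
  expect_gte(max(abs(rowSums(ig4$scores) - ig4$completeness)), max(res) - 1e-9)
  expect_error(integrated_gradients(fit$model, fit$src_vocab, fit$tgt_vocab,
                                    src, tgt, m_steps = 0), "m_steps")
})

test_that("a model with a zero output head attributes nothing", {
  fit <- fixture_tiny_fit()
  mols <- fixture_tiny_fit_records()
  zeroed <- fit$model
  zeroed$params[["out.W"]][] <- 0
  zeroed$params[["out.b"]][] <- 0
  src <- featurize(mols$smiles[3], fit$spec)$tokens
  tgt <- tokenize_smiles(mols$smiles[3])[1:5]
  ig <- integrated_gradients(zeroed, fit$src_vocab, fit$tgt_vocab, src, tgt,
                             m_steps = 8)
  expect_equal(max(abs(ig$scores)), 0)
})

test_that("attention maps are row-normalized softmax aggregates", {
  fit <- fixture_tiny_fit()
  mols <- fixture_tiny_fit_records()
  src <- featurize(mols$smiles[4], fit$spec)$tokens
  tgt <- tokenize_smiles(mols$smiles[4])
  am <- attention_map(fit$model, fit$src_vocab, fit$tgt_vocab, src, tgt)
  expect_identical(dim(am$scores), c(length(tgt), length(src)))
  expect_lt(max(abs(rowSums(am$scores) - 1)), 1e-6)
  expect_true(all(am$scores >= 0))
  # head aggregation is the arithmetic mean of per-head maps
  H <- fit$model$cfg$n_heads
  per_head <- lapply(seq_len(H), function(h)
    attention_map(fit$model, fit$src_vocab, fit$tgt_vocab, src, tgt,
                  head_agg = h)$scores)
  expect_equal(am$scores, Reduce(`+`, per_head) / H, tolerance = 1e-12)
  # single-source-token input puts all weight on that token
  am1 <- attention_map(fit$model, fit$src_vocab, fit$tgt_vocab,
                       src[1], tgt[1:3])
  expect_equal(unname(am1$scores[, 1]), rep(1, 3), tolerance = 1e-9)
})

test_that("attribution matrices export as labelled TSV", {
  fit <- fixture_tiny_fit()
  mols <- fixture_tiny_fit_records()
  src <- featurize(mols$smiles[5], fit$spec)$tokens
  tgt <- tokenize_smiles(mols$smiles[5])
  am <- attention_map(fit$model, fit$src_vocab, fit$tgt_vocab, src, tgt)
  f <- tempfile(fileext = ".tsv")
  write_attribution_tsv(am, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_identical(nrow(back), length(tgt))
  expect_identical(ncol(back), length(src) + 1L)
})
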