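# The fp_translator modelling interface and checkpoints.

test_that("fitting returns a usable model object with standard methods", {
  fit <- fixture_tiny_fit()
  expect_s3_class(fit, "fp_translator")
  expect_identical(fit$spec$name, "AEs")
  expect_identical(fit$representation, "SMILES")
  expect_output(print(fit), "transformer")
  s <- summary(fit)
  expect_s3_class(s, "summary.fp_translator")
  expect_identical(s$n_train, 30L)
  expect_gt(s$n_parameters, 0)
  expect_output(print(s), "final loss")
  expect_identical(count_parameters(fit$model),
                   sum(vapply(coef(fit), length, integer(1))))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), -tail(fit$history$loss, 1))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("predict produces well-formed prediction records", {
  fit <- fixture_tiny_fit()
  mols <- fixture_tiny_fit_records()[1:4, ]
  pr <- predict(fit, mols, beam_size = 2)
  expect_identical(names(pr), c("id", "ground_truth", "prediction",
                                "representation", "valid", "tc_primary"))
  expect_identical(pr$id, mols$id)
  expect_identical(pr$ground_truth, mols$smiles)
  expect_true(all(pr$tc_primary >= 0 & pr$tc_primary <= 1))
  # character input works too
  pr2 <- predict(fit, mols$smiles[1], beam_size = 1)
  expect_identical(nrow(pr2), 1L)
})

test_that("checkpoints round-trip and validate their config hash", {
  fit <- fixture_tiny_fit()
  f <- tempfile(fileext = ".rds")
  save_translator(fit, f)
  back <- load_translator(f)
  expect_identical(back$model$params, fit$model$params)
  expect_identical(back$src_vocab$tokens, fit$src_vocab$tokens)
  expect_identical(back$spec$name, fit$spec$name)
  # same predictions from the reloaded model
  mols <- fixture_tiny_fit_records()[1:2, ]
  expect_identical(predict(back, mols, beam_size = 1)$prediction,
                   predict(fit, mols, beam_size = 1)$prediction)
  # corrupting the stored config breaks the hash check
  x <- readRDS(f)
  x$cfg_json <- sub("\"n_heads\":2", "\"n_heads\":4", x$cfg_json)
  saveRDS(x, f)
  expect_error(load_translator(f), "hash")
})

test_that("SELFIES-representation models emit only valid predictions", {
  mols <- fixture_tiny_fit_records()
  fit <- fp_translator(
    mols[1:12, ], spec = "ECFP2", representation = "SELFIES",
    model_cfg = model_config(n_layers = 1, n_heads = 2, d_model = 24,
                             d_ff = 48, dropout = 0.1,
                             max_len_src = 120, max_len_tgt = 120),
    train_cfg = train_config(tokens_per_batch = 1200, max_steps = 40,
                             checkpoint_every = 10000, seed = 555),
    sched_cfg = sched_config(warmup_steps = 20, cycle_steps = 60))
  pr <- predict(fit, mols[1:12, ], beam_size = 1, max_len = 60)
  # an undertrained model may fail to terminate (flagged via valid = FALSE),
  # but every terminated SELFIES prediction decodes to a molecule
  done <- pr$valid
  if (any(done)) {
    expect_true(all(is_valid_molstring(pr$prediction[done], "SELFIES")))
  }
  dec <- vapply(pr$prediction[done], selfies_decode, character(1))
  expect_true(all(is_valid_molstring(dec)))
})
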