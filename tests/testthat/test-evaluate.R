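# Evaluation suite: exactness, breakdown partition, bias matrix,
# significance thresholds, stereo-error profile.

test_that("Tanimoto exactness counts invalids in the denominator only", {
  recs <- fixture_breakdown_records()
  # rows: exact, non-canonical, stereo-flip, chain homolog, miss, invalid
  expect_equal(tanimoto_exactness(recs, "AEs"), 100 * 4 / 6)
  all_bad <- recs; all_bad$valid <- FALSE
  expect_equal(tanimoto_exactness(all_bad, "AEs"), 0)
  perfect <- recs[1, ]; perfect$valid <- TRUE
  for (nm in metric_fingerprint_names()) {
    expect_equal(tanimoto_exactness(perfect, nm), 100)
  }
  expect_error(tanimoto_exactness(recs[0, ]), "empty")
})

test_that("the breakdown classifies each adversarial record correctly", {
  recs <- fixture_breakdown_records()
  br <- breakdown(recs)
  expect_identical(br$classes,
                   c("string_exact", "noncanonical", "stereo", "others",
                     "not_exact", "invalid"))
  expect_equal(br$pct_string_exact + br$pct_noncanonical + br$pct_stereo +
                 br$pct_others, br$pct_tc_exact)
  expect_equal(br$pct_tc_exact, 100 * 4 / 6)
  expect_equal(br$pct_invalid, 100 / 6)
  expect_true(br$mean_tc >= 0 && br$mean_tc <= 1)
  # invalid contributes 0 to the mean Tc
  tc_by_hand <- c(1, 1, 1, 1, tanimoto_smiles("CCC", "CCO", "AEs"), 0)
  expect_equal(br$mean_tc, mean(tc_by_hand))
  expect_output(print(br), "String exact")
})

test_that("the breakdown partition identity holds on random record mixes", {
  mols <- fixture_corpus(1000)
  set.seed(99)
  idx <- sample(nrow(mols), 30)
  # predictions: a mix of copies, stereo-strips and unrelated molecules
  pred <- mols$smiles[idx]
  pred[1:10] <- mols$smiles[sample(nrow(mols), 10)]
  pred[11:15] <- canonicalize_smiles(pred[11:15], keep_stereo = FALSE)
  recs <- data.frame(id = as.character(seq_along(idx)),
                     ground_truth = mols$smiles[idx], prediction = pred,
                     representation = "SMILES",
                     valid = is_valid_molstring(pred),
                     tc_primary = NA_real_, stringsAsFactors = FALSE)
  br <- breakdown(recs)
  expect_equal(br$pct_string_exact + br$pct_noncanonical + br$pct_stereo +
                 br$pct_others, br$pct_tc_exact, tolerance = 1e-12)
  not_exact <- 100 - br$pct_tc_exact - br$pct_invalid
  expect_equal(100 * sum(br$classes == "not_exact") / br$n_total, not_exact)
  # exactness under any metric is at least the string-exact share
  for (nm in c("MACCS", "ECFP4", "TT")) {
    expect_gte(tanimoto_exactness(recs, nm), br$pct_string_exact - 1e-9)
  }
})

test_that("bias-matrix cells equal independent per-metric recomputations", {
  recs <- fixture_breakdown_records()
  bm <- bias_matrix(list(toy = recs, toy2 = recs[1:3, ]))
  expect_identical(dim(bm), c(2L, 15L))
  expect_identical(colnames(bm), metric_fingerprint_names())
  for (j in seq_len(ncol(bm))) {
    expect_equal(bm["toy", j],
                 tanimoto_exactness(recs, metric_fingerprint_names()[j]))
  }
  expect_true(all(bm >= 0 & bm <= 100))
  # a perfect model scores 100 in every column
  perfect <- recs[1, ]
  expect_true(all(bias_matrix(list(p = perfect)) == 100))
  # string-exact share lower-bounds every cell in its row
  se <- 100 * mean(recs$prediction == recs$ground_truth)
  expect_true(all(bm["toy", ] >= se - 1e-9))
})

test_that("significance thresholds equal the brute-force sorted quantile", {
  mols <- fixture_corpus(1000)[1:60, ]
  th <- significance_threshold(mols, "AEs", p = 0.01, n_pairs = 1000,
                               seed = 77)
  sorted <- sort(th$similarities)
  expect_identical(th$tc_threshold, sorted[990])
  expect_true(th$tc_threshold >= 0 && th$tc_threshold <= 1)
  # no self-pairs were sampled: check via an identical-corpus threshold
  same <- mols[rep(1, 10), ]
  same$smiles <- rep(mols$smiles[1], 10)
  expect_equal(significance_threshold(same, "AEs", 0.01, 200,
                                      seed = 1)$tc_threshold, 1.0)
  # p = 1 gives the minimum sampled similarity
  expect_identical(
    significance_threshold(mols, "AEs", p = 1, n_pairs = 500, seed = 3)$tc_threshold,
    min(significance_threshold(mols, "AEs", p = 1, n_pairs = 500,
                               seed = 3)$similarities))
  # monotone non-increasing in p
  t01 <- significance_threshold(mols, "MACCS", 0.01, 500, seed = 5)$tc_threshold
  t10 <- significance_threshold(mols, "MACCS", 0.10, 500, seed = 5)$tc_threshold
  t50 <- significance_threshold(mols, "MACCS", 0.50, 500, seed = 5)$tc_threshold
  expect_gte(t01, t10)
  expect_gte(t10, t50)
  # deterministic per seed
  expect_identical(th$tc_threshold,
                   significance_threshold(mols, "AEs", 0.01, 1000,
                                          seed = 77)$tc_threshold)
  expect_error(significance_threshold(mols[1, ], "AEs"), "at least 2")
})

test_that("the stereo-error profile separates its cases", {
  recs <- data.frame(
    id = c("rev", "miss", "spur"),
    ground_truth = c("C/C=C/C", "C[C@@H](N)C(=O)O", "CC(N)C(=O)O"),
    prediction = c("C/C=C\\C", "CC(N)C(=O)O", "C[C@@H](N)C(=O)O"),
    representation = "SMILES", valid = TRUE, tc_primary = NA_real_,
    stringsAsFactors = FALSE)
  prof <- stereo_error_profile(recs)
  expect_identical(prof[["reversed"]], 1L)
  expect_identical(prof[["missing"]], 1L)
  expect_identical(prof[["spurious"]], 1L)
  expect_identical(prof[["mixed"]], 0L)
  expect_identical(sum(prof), 3L)
})
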