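# Synthetic corpus: generation, filtering, diversity selection, splits.

test_that("generation honours the requested size, uniqueness and cap", {
  expect_identical(nrow(generate_molecules(corpus_config(0))), 0L)
  mols <- fixture_corpus(1000)
  expect_identical(nrow(mols), 1000L)
  expect_false(anyDuplicated(mols$smiles) > 0)
  expect_true(all(mols$heavy_atoms <= 50L))
  expect_identical(nrow(filter_by_heavy_atoms(mols, 50L)), nrow(mols))
  # records re-canonicalize to themselves
  sub <- mols$smiles[1:25]
  expect_identical(canonicalize_smiles(sub), sub)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_molecules(corpus_config(100, seed = 7))
  b <- generate_molecules(corpus_config(100, seed = 7))
  expect_identical(a, b)
  c_ <- generate_molecules(corpus_config(100, seed = 8))
  expect_false(identical(a$smiles, c_$smiles))
})

test_that("exhausting the attempt budget is a diagnosed failure", {
  expect_error(
    generate_molecules(corpus_config(50, max_generation_attempts = 5,
                                     seed = 1)),
    "exhausted")
})

test_that("the stereo fraction approaches its target", {
  mols <- fixture_corpus(1000)
  expect_lt(abs(mean(mols$has_stereo) - 0.3), 0.1)
  expect_identical(mols$has_stereo, grepl("[@/\\\\]", mols$smiles))
})

test_that("the heavy-atom filter is inclusive and order-preserving", {
  recs <- data.frame(id = c("a", "b", "c", "d"),
                     smiles = c("x", "y", "z", "w"),
                     heavy_atoms = c(50L, 51L, 3L, 50L),
                     has_stereo = FALSE, stringsAsFactors = FALSE)
  kept <- filter_by_heavy_atoms(recs, 50L)
  expect_identical(kept$id, c("a", "c", "d"))   # 50 kept, 51 removed
  expect_identical(nrow(filter_by_heavy_atoms(recs[0, ], 50L)), 0L)
  expect_error(filter_by_heavy_atoms(recs, 0L))
})

test_that("diversity selection matches an exhaustive greedy oracle", {
  mols <- fixture_corpus(1000)
  base <- mols[1:5, ]
  cand <- mols[6:25, ]
  sel <- select_diverse_by_atom_types(cand, base, budget = 8L)
  # brute-force greedy recomputation
  feats <- lapply(cand$smiles, fp2mol:::atom_type_features)
  covered <- unique(unlist(lapply(base$smiles, fp2mol:::atom_type_features)))
  expected <- integer(0)
  remaining <- seq_len(nrow(cand))
  for (k in 1:8) {
    gains <- vapply(remaining, function(i)
      length(setdiff(feats[[i]], covered)), integer(1))
    if (!length(gains) || max(gains) == 0) break
    pick <- remaining[which.max(gains)]
    expected <- c(expected, pick)
    covered <- union(covered, feats[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  expect_identical(sel$id, cand$id[expected])
  # coverage is no worse than any random subset of the same size
  cover_of <- function(idx) length(unique(unlist(feats[idx])))
  full <- select_diverse_by_atom_types(cand, cand[0, ], budget = nrow(cand))
  set.seed(1)
  for (r in 1:10) {
    idx <- sample(nrow(cand), length(expected))
    sel_cov <- length(unique(unlist(c(
      lapply(base$smiles, fp2mol:::atom_type_features), feats[expected]))))
    rnd_cov <- length(unique(unlist(c(
      lapply(base$smiles, fp2mol:::atom_type_features), feats[idx]))))
    expect_gte(sel_cov, rnd_cov)
  }
})

test_that("candidates adding no coverage are never selected", {
  mols <- fixture_corpus(1000)
  base <- mols[1:10, ]
  sel <- select_diverse_by_atom_types(base, base, budget = 10L)
  expect_identical(nrow(sel), 0L)
  expect_identical(nrow(select_diverse_by_atom_types(base, base[0, ], 0L)), 0L)
})

test_that("splits are uniform, disjoint and seed-deterministic", {
  mols <- fixture_corpus(1000)[1:100, ]
  sp <- split_corpus(mols, test_size = 10, seed = 5)
  expect_identical(nrow(sp$train), 90L)
  expect_identical(nrow(sp$test), 10L)
  expect_length(intersect(sp$train$smiles, sp$test$smiles), 0L)
  sp2 <- split_corpus(mols, test_size = 10, seed = 5)
  expect_identical(sp$test$id, sp2$test$id)
  sp0 <- split_corpus(mols, test_size = 0)
  expect_identical(nrow(sp0$train), 100L)
  expect_error(split_corpus(mols, 101), "test_size")
})

test_that("SMILES files and manifests round-trip", {
  mols <- fixture_corpus(1000)[1:20, ]
  f <- tempfile(fileext = ".smi")
  write_smiles_file(mols, f)
  back <- read_smiles_file(f)
  expect_identical(back$smiles, mols$smiles)
  expect_identical(back$id, mols$id)
  mf <- tempfile(fileext = ".json")
  write_corpus_manifest(corpus_config(20, seed = 1), mols, mf)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  expect_identical(man$n_generated, 20L)
  expect_equal(man$stereo_fraction, mean(mols$has_stereo))
})
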