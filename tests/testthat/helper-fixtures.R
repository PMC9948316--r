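# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code from fixed seeds; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixture_cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a drug-like synthetic corpus used by round-trip and property tests
fixture_corpus <- function(n = 1000) {
  fixture_cached(paste0("corpus", n), function() {
    generate_molecules(corpus_config(n_molecules = n, seed = 424242))
  })
}

# a handful of hand-picked molecules covering the featurizer edge cases
fixture_panel <- function() {
  c(
    ethanol = "CCO",
    benzene = "c1ccccc1",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    alanine = "C[C@@H](C(=O)O)N",
    butene = "C/C=C/C",
    nitro = "CC[N+](=O)[O-]",
    pyridine = "c1ccncc1",
    isobutane = "CC(C)C"
  )
}

# a small trained translator shared by decoding/attribution tests:
# 30 molecules, tiny transformer, enough steps to be non-degenerate
fixture_tiny_fit <- function() {
  fixture_cached("tiny_fit", function() {
    mols <- generate_molecules(corpus_config(n_molecules = 30, seed = 777))
    fp_translator(
      mols, spec = "AEs", representation = "SMILES",
      model_cfg = model_config(n_layers = 2, n_heads = 2, d_model = 32,
                               d_ff = 64, dropout = 0.1,
                               max_len_src = 150, max_len_tgt = 100),
      train_cfg = train_config(tokens_per_batch = 1500, max_steps = 150,
                               checkpoint_every = 10000, seed = 778),
      sched_cfg = sched_config(warmup_steps = 60, cycle_steps = 200))
  })
}

fixture_tiny_fit_records <- function() {
  fixture_cached("tiny_fit_records", function() {
    generate_molecules(corpus_config(n_molecules = 30, seed = 777))
  })
}

# hand-built prediction records exercising every breakdown category:
# string-exact, non-canonical, stereo-flipped, equal-fingerprint chain
# homologs ("others"), a Tc<1 miss and a syntactically invalid prediction
fixture_breakdown_records <- function() {
  data.frame(
    id = sprintf("T%02d", 1:6),
    ground_truth = c("CCO", "CCO", "C/C=C/C", "CCCCCCCC", "CCO", "CCO"),
    prediction = c("CCO", "OCC", "C/C=C\\C", "CCCCCCC", "CCC", "C(("),
    representation = "SMILES",
    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    tc_primary = c(1, 1, NA, 1, NA, 0),
    stringsAsFactors = FALSE
  )
}

expect_same_molecule <- function(a, b) {
  expect_identical(canonicalize_smiles(a), canonicalize_smiles(b))
}
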